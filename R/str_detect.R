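#' Default detection thresholds per unit size
#'
#' Minimum array length is `max(12, 3 * u)` bp and minimum copy number is
#' `min_len[u] / u`, for unit sizes `u` in 1..10. A 12 bp floor keeps
#' trivially short tracts out; three full units keep larger motifs honest.
#'
#' @param min_unit,max_unit Unit-size range (defaults 1 and 10 bp).
#' @return List with numeric vectors `min_len` and `min_copies`, named by
#'   unit size.
#' @export
str_default_thresholds <- function(min_unit = 1L, max_unit = 10L) {
  u <- seq.int(min_unit, max_unit)
  min_len <- pmax(12, 3 * u)
  list(min_len = stats::setNames(min_len, u),
       min_copies = stats::setNames(min_len / u, u))
}

#' Detect perfect short tandem repeats
#'
#' Finds every maximal perfect tandem array with unit size in
#' `[min_unit, max_unit]` meeting the length/copy thresholds. The reported
#' unit size is the minimal period of the tract (an `(AC)n` array is never
#' also reported at u = 4), arrays never span `N`, and partial trailing
#' units count toward the array length (`ACACA` has copy number 2.5).
#'
#' @param seqs A `DNAStringSet`, `DNAString`, or (named) character vector.
#' @param min_unit,max_unit Unit-size range in bp (defaults 1 and 10).
#' @param thresholds List with `min_len` and `min_copies` vectors named by
#'   unit size, as from [str_default_thresholds()].
#' @return `GRanges` with metadata columns `unit_size`, `motif` (canonical),
#'   `copy_number`, `array_bp`.
#' @export
find_strs <- function(seqs, min_unit = 1L, max_unit = 10L,
                      thresholds = str_default_thresholds(min_unit, max_unit)) {
  if (min_unit > max_unit) stop("min_unit > max_unit")
  if (min_unit < 1L) stop("min_unit must be >= 1")
  us <- as.character(seq.int(min_unit, max_unit))
  if (!all(us %in% names(thresholds$min_len)) ||
      !all(us %in% names(thresholds$min_copies)))
    stop("thresholds must cover every unit size in range")
  if (inherits(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(list(seqs))
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  per_seq <- lapply(seq_along(seqs), function(i) {
    hits <- .scan_one(as.character(seqs[[i]]), min_unit, max_unit, thresholds)
    if (nrow(hits) > 0) hits$seq_id <- names(seqs)[i]
    hits
  })
  hits <- do.call(rbind, per_seq[vapply(per_seq, nrow, integer(1)) > 0])
  if (is.null(hits) || nrow(hits) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$unit_size <- integer(0); gr$motif <- character(0)
    gr$copy_number <- numeric(0); gr$array_bp <- integer(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(hits$seq_id,
                               IRanges::IRanges(hits$start, hits$end))
  gr$unit_size <- hits$unit_size
  gr$motif <- hits$motif
  gr$copy_number <- hits$copy_number
  gr$array_bp <- hits$array_bp
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

# Scan one sequence (character scalar) for maximal perfect arrays.
# Period-u candidates come from runs of s[i] == s[i + u]; the tract is then
# kept only if u is its minimal period and thresholds are met.
.scan_one <- function(s, min_unit, max_unit, thresholds) {
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_size = integer(0), motif = character(0),
                      copy_number = numeric(0), array_bp = integer(0))
  if (n < 2) return(empty)
  raw <- charToRaw(s)
  valid <- raw %in% charToRaw("ACGT")
  out <- vector("list", max_unit)
  for (u in seq.int(min_unit, min(max_unit, n - 1L))) {
    min_len <- thresholds$min_len[[as.character(u)]]
    eq <- raw[seq_len(n - u)] == raw[seq.int(u + 1L, n)] &
      valid[seq_len(n - u)] & valid[seq.int(u + 1L, n)]
    r <- rle(eq)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- r$values & (r$lengths + u) >= min_len
    if (!any(keep)) next
    tr_start <- starts_idx[keep]
    tr_end <- ends_idx[keep] + u          # tract is [start, end] inclusive
    ok <- vapply(seq_along(tr_start), function(k) {
      i <- tr_start[k]; j <- tr_end[k]
      if (!all(valid[i:j])) return(FALSE)
      # minimal-period rule: reject if any smaller period fits the tract
      for (p in seq_len(u - 1L)) {
        if (all(raw[i:(j - p)] == raw[(i + p):j])) return(FALSE)
      }
      TRUE
    }, logical(1))
    if (!any(ok)) next
    i <- tr_start[ok]; j <- tr_end[ok]
    len <- j - i + 1L
    out[[u]] <- data.frame(
      start = i, end = j, unit_size = u,
      motif = canonical_motif(substring(s, i, i + u - 1L)),
      copy_number = len / u, array_bp = len)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  cn <- thresholds$min_copies
  res <- if (length(out) > 0) do.call(rbind, out) else empty
  if (nrow(res) > 0)
    res <- res[res$copy_number >= cn[as.character(res$unit_size)], ,
               drop = FALSE]
  res
}

#' Canonical representative of a repeat unit
#'
#' The lexicographically smallest string among all rotations of the unit
#' and all rotations of its reverse complement, so that e.g. `GA`, `AG`,
#' `TC` and `CT` all map to `AG`.
#'
#' @param unit Character vector of repeat units (length 1-10, ACGT only).
#' @return Character vector of canonical motifs.
#' @export
canonical_motif <- function(unit) {
  unit <- toupper(unit)
  if (any(grepl("[^ACGT]", unit)))
    stop("canonical_motif: units must contain only A, C, G, T")
  if (any(nchar(unit) < 1L | nchar(unit) > 10L))
    stop("canonical_motif: unit length must be 1-10")
  vapply(unit, function(w) {
    u <- nchar(w)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(w, "")[[1]]), collapse = ""))
    dbl <- paste0(w, w); dblrc <- paste0(rc, rc)
    rots <- c(substring(dbl, 1:u, 1:u + u - 1L),
              substring(dblrc, 1:u, 1:u + u - 1L))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Clip STR loci to a set of regions
#'
#' Intersects each locus with normalized (sorted, merged) regions. Clipped
#' loci have `array_bp` and `copy_number` recomputed from the clipped
#' interval; loci fully outside the regions are dropped. A locus spanning a
#' gap between two regions yields one clipped locus per region.
#'
#' @param loci `GRanges` from [find_strs()].
#' @param regions `GRanges` of target regions (e.g. merged CDS).
#' @return Clipped `GRanges` with the same metadata columns.
#' @export
strs_in_regions <- function(loci, regions) {
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(loci, regions, ignore.strand = TRUE)
  clipped <- IRanges::pintersect(
    GenomicRanges::granges(loci)[S4Vectors::queryHits(ov)],
    regions[S4Vectors::subjectHits(ov)], ignore.strand = TRUE)
  out <- clipped
  S4Vectors::mcols(out) <- S4Vectors::mcols(loci)[S4Vectors::queryHits(ov), ,
                                                  drop = FALSE]
  out$hit <- NULL
  out$array_bp <- BiocGenerics::width(out)
  out$copy_number <- out$array_bp / out$unit_size
  out
}

#' STR density and frequency statistics
#'
#' Per unit size and in total: locus count, array bp, density
#' (`1e6 * array_bp_total / region_bp`, bp/Mbp) and frequency
#' (`1e6 * loci_count / region_bp`, loci/Mbp). For the bp totals,
#' overlapping arrays of different unit size are resolved by giving shared
#' bases to the smaller unit, so the total row never double-counts; locus
#' counts are of unresolved maximal arrays.
#'
#' @param loci `GRanges` from [find_strs()] (optionally clipped by
#'   [strs_in_regions()]).
#' @param region_bp Total size of the surveyed region in bp (> 0).
#' @param region_label Label for the region (e.g. `"assembly"`, `"CDS"`).
#' @return `data.frame` with one row per unit size plus a `total` row.
#' @export
str_statistics <- function(loci, region_bp, region_label = "assembly") {
  if (region_bp <= 0) stop("region_bp must be > 0")
  us <- sort(unique(loci$unit_size))
  claimed <- GenomicRanges::GRanges()
  rows <- lapply(us, function(u) {
    sel <- loci[loci$unit_size == u]
    merged <- GenomicRanges::reduce(GenomicRanges::granges(sel),
                                    ignore.strand = TRUE)
    own <- GenomicRanges::setdiff(merged, claimed, ignore.strand = TRUE)
    claimed <<- GenomicRanges::union(claimed, merged, ignore.strand = TRUE)
    data.frame(unit_size = as.character(u),
               loci_count = length(sel),
               array_bp_total = sum(BiocGenerics::width(own)))
  })
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(unit_size = character(0), loci_count = integer(0),
               array_bp_total = integer(0))
  tab <- rbind(tab, data.frame(unit_size = "total",
                               loci_count = sum(tab$loci_count),
                               array_bp_total = sum(tab$array_bp_total)))
  tab$density <- 1e6 * tab$array_bp_total / region_bp
  tab$frequency <- 1e6 * tab$loci_count / region_bp
  tab$region_label <- region_label
  tab$region_bp <- region_bp
  tab
}
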
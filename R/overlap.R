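#' Per-gene STR overlap summary
#'
#' An STR counts for a gene when it overlaps the chosen scope (whole gene
#' span, or merged CDS) by at least 1 bp.
#'
#' @param models A `gene_models` object.
#' @param loci `GRanges` of STR loci from [find_strs()].
#' @param scope `"gene_span"` (default) or `"cds"`.
#' @return `data.frame` with columns `gene_id`, `strs_total`, `has_str`,
#'   and one `u<k>` column per unit size present in `loci`.
#' @export
genes_with_strs <- function(models, loci, scope = c("gene_span", "cds")) {
  scope <- match.arg(scope)
  gene_ids <- names(models$genes)
  if (length(loci) > 0 &&
      !any(as.character(GenomicRanges::seqnames(loci)) %in%
           as.character(GenomicRanges::seqnames(models$genes))))
    warning("no shared seq_id between genes and STR loci")
  us <- sort(unique(loci$unit_size))
  ucols <- paste0("u", us, recycle0 = TRUE)
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(us),
                   dimnames = list(gene_ids, ucols))
  if (length(loci) > 0) {
    target <- if (scope == "gene_span") models$genes else models$cds
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(target, loci, ignore.strand = TRUE))
    gidx <- S4Vectors::queryHits(ov)
    lidx <- S4Vectors::subjectHits(ov)
    if (length(gidx) > 0) {
      tab <- table(factor(gene_ids[gidx], levels = gene_ids),
                   factor(paste0("u", loci$unit_size[lidx]),
                          levels = ucols))
      counts <- unclass(tab)
      storage.mode(counts) <- "integer"
    }
  }
  out <- data.frame(gene_id = gene_ids,
                    strs_total = as.integer(rowSums(counts)),
                    row.names = NULL)
  out$has_str <- out$strs_total > 0L
  cbind(out, as.data.frame(counts, row.names = NULL))
}

#' Genes with a size-3 indel inside a trinucleotide STR
#'
#' A gene is counted when at least one retained variant of class `INDEL`
#' with `|indel_size| == 3` has its anchor inside a trinucleotide STR locus
#' that overlaps the gene. The anchor is the first affected base after the
#' shared REF/ALT prefix (left-aligned VCF convention): `pos + 1` for the
#' anchored-base representation used by VCF indels.
#'
#' @param models A `gene_models` object.
#' @param tri_loci `GRanges` of trinucleotide loci (`unit_size == 3`).
#' @param variants Filtered variant `data.frame` from [read_variants()].
#' @param scope `"gene_span"` (default) or `"cds"`.
#' @return List with `count` (number of genes) and `flags` (named logical
#'   per gene).
#' @export
tri_indel_gene_overlap <- function(models, tri_loci, variants,
                                   scope = c("gene_span", "cds")) {
  scope <- match.arg(scope)
  if (length(tri_loci) > 0 && any(tri_loci$unit_size != 3L))
    stop("tri_loci must have unit_size == 3")
  gene_ids <- names(models$genes)
  flags <- stats::setNames(rep(FALSE, length(gene_ids)), gene_ids)
  v <- variants[variants$var_class == "INDEL" &
                  abs(variants$indel_size) == 3L, , drop = FALSE]
  if (nrow(v) > 0 && length(tri_loci) > 0) {
    anchors <- GenomicRanges::GRanges(v$seq_id,
                                      IRanges::IRanges(v$pos + 1L, v$pos + 1L))
    # host arrays: trinucleotide loci containing an anchored size-3 indel;
    # a gene is counted when it overlaps any host array
    host <- tri_loci[unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(anchors, tri_loci, ignore.strand = TRUE)))]
    target <- if (scope == "gene_span") models$genes else models$cds
    gidx <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(target, host, ignore.strand = TRUE)))
    flags[gene_ids[gidx]] <- TRUE
  }
  list(count = sum(flags), flags = flags)
}

#' Per-class variant counts and per-bp rates
#'
#' Rates are nucleotide-diversity-style: `count / assembly_bp`.
#'
#' @param variants Filtered variant `data.frame` from [read_variants()], or
#'   a named integer vector of per-class counts (names among SNP, MNP,
#'   INDEL, COMPLEX).
#' @param assembly_bp Assembly length in bp (> 0).
#' @return `data.frame` with columns `var_class`, `count`, `rate`.
#' @export
variant_rates <- function(variants, assembly_bp) {
  if (assembly_bp <= 0) stop("assembly_bp must be > 0")
  classes <- c("SNP", "MNP", "INDEL", "COMPLEX")
  if (is.data.frame(variants)) {
    counts <- table(factor(variants$var_class, levels = classes))
    counts <- stats::setNames(as.integer(counts), classes)
  } else {
    counts <- stats::setNames(rep(0L, 4), classes)
    counts[names(variants)] <- as.integer(variants)
  }
  data.frame(var_class = classes,
             count = unname(counts),
             rate = unname(counts) / assembly_bp,
             row.names = NULL)
}
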
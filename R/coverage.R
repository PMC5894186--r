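#' Read a read-depth table
#'
#' Accepts either a per-base table (columns `seq_id`, `pos`, `depth`;
#' samtools-depth-compatible, zero-depth positions included) or a
#' pre-averaged summary (columns `seq_id`, `mean_depth`, `length`). The
#' format is taken from the header when present, otherwise from
#' `format`.
#'
#' @param path Path to a TSV.
#' @param format `"auto"` (header-based), `"per_base"` or `"summary"`.
#' @return `data.frame` in the input's shape with canonical column names.
#' @export
read_depth_table <- function(path, format = c("auto", "per_base",
                                              "summary")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1)
  has_header <- grepl("seq_id", first)
  if (format == "auto") {
    if (!has_header)
      stop("cannot auto-detect depth format without a header; pass format=")
    format <- if (grepl("mean_depth", first)) "summary" else "per_base"
  }
  cols <- if (format == "per_base")
    c(seq_id = "character", pos = "integer", depth = "numeric")
  else c(seq_id = "character", mean_depth = "numeric", length = "integer")
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           col.names = names(cols), colClasses = unname(cols))
  tab
}

#' Per-sequence mean depth and assembly mean
#'
#' @param depth `data.frame` from [read_depth_table()] (either shape).
#' @param seq_lengths Named integer vector of sequence lengths; required
#'   for per-base input so sequences with no depth rows still appear (mean
#'   0, with a warning), optional for summary input.
#' @return `data.frame` with `seq_id`, `length`, `mean_depth`, plus
#'   attribute `assembly_mean` = total depth / total length.
#' @export
per_sequence_depth <- function(depth, seq_lengths = NULL) {
  if ("pos" %in% names(depth)) {
    if (is.null(seq_lengths))
      stop("seq_lengths required for per-base depth input")
    tot <- tapply(depth$depth, depth$seq_id, sum)
    out <- data.frame(seq_id = names(seq_lengths),
                      length = unname(seq_lengths))
    out$total <- as.numeric(tot[out$seq_id])
    missing <- is.na(out$total)
    if (any(missing)) {
      warning(sum(missing), " sequence(s) with no depth rows: mean 0")
      out$total[missing] <- 0
    }
    out$mean_depth <- out$total / out$length
    out$total <- NULL
  } else {
    out <- data.frame(seq_id = depth$seq_id, length = depth$length,
                      mean_depth = depth$mean_depth)
  }
  attr(out, "assembly_mean") <-
    sum(out$mean_depth * out$length) / sum(out$length)
  out
}

#' Normalize per-sequence depth by the assembly mean
#'
#' @param records Output of [per_sequence_depth()].
#' @return The records with a `normalized_depth` column; the length-
#'   weighted mean of `normalized_depth` is 1 by construction.
#' @export
normalize_depth <- function(records) {
  am <- attr(records, "assembly_mean")
  if (is.null(am))
    am <- sum(records$mean_depth * records$length) / sum(records$length)
  records$normalized_depth <- records$mean_depth / am
  attr(records, "assembly_mean") <- am
  records
}

#' Flag collapsed sequences and estimate copy numbers
#'
#' A sequence is flagged as a candidate collapsed repeat when its
#' normalized depth exceeds `threshold` and it carries at least one domain
#' hit. The naive copy estimate multiplies the hit count by the rounded
#' normalized depth (a fractional estimate is emitted alongside). Also
#' returns the length-versus-normalized-depth table for domain-bearing
#' sequences (log10 length, as plotted in collapse diagnostics).
#'
#' @param records Output of [normalize_depth()].
#' @param domain_hits `data.frame` with a `seq_id` column (e.g. `hits`
#'   from [census()]).
#' @param threshold Normalized-depth flag threshold (default 2.0; the
#'   conservative 5x preset flags only gross collapse).
#' @return List with `records` (plus `n_hits`, `flagged_collapsed`,
#'   `depth_multiplier`, `est_copies`, `est_copies_fractional`) and
#'   `diagnostics` (`seq_id`, `log10_length`, `normalized_depth`,
#'   `n_hits` for sequences with hits).
#' @export
flag_collapsed <- function(records, domain_hits, threshold = 2.0) {
  if (threshold <= 1)
    warning("threshold <= 1: flags will be dominated by depth noise")
  hit_counts <- table(domain_hits$seq_id)
  records$n_hits <- as.integer(hit_counts[records$seq_id])
  records$n_hits[is.na(records$n_hits)] <- 0L
  records$flagged_collapsed <- records$normalized_depth > threshold &
    records$n_hits > 0L
  records$depth_multiplier <- pmax(1, round(records$normalized_depth))
  records$est_copies <- records$n_hits * records$depth_multiplier
  records$est_copies_fractional <- records$n_hits *
    pmax(1, records$normalized_depth)
  diag <- records[records$n_hits > 0L, , drop = FALSE]
  diagnostics <- data.frame(seq_id = diag$seq_id,
                            log10_length = log10(diag$length),
                            normalized_depth = diag$normalized_depth,
                            n_hits = diag$n_hits)
  list(records = records, diagnostics = diagnostics)
}
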
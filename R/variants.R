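#' Classify a variant from its REF/ALT alleles
#'
#' Classification contract: equal length 1 -> `SNP`; equal length > 1 ->
#' `MNP`; one allele a strict prefix of the other (pure insertion or
#' deletion) -> `INDEL` with signed size `nchar(alt) - nchar(ref)`;
#' anything else (composite insertion and substitution events) ->
#' `COMPLEX` with size 0.
#'
#' @param ref,alt Character vectors of REF and ALT alleles (DNA, non-empty).
#' @return `data.frame` with columns `var_class` (factor with levels
#'   SNP, MNP, INDEL, COMPLEX) and `indel_size` (integer, 0 unless INDEL).
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("ref and alt must be non-empty")
  if (any(grepl("[^ACGTN]", c(ref, alt))))
    stop("non-DNA characters in ref/alt")
  nr <- nchar(ref); na <- nchar(alt)
  cls <- rep("COMPLEX", length(ref))
  sz <- rep(0L, length(ref))
  cls[nr == 1L & na == 1L] <- "SNP"
  cls[nr == na & nr > 1L] <- "MNP"
  shorter_is_prefix <- (nr != na) &
    (substr(ref, 1L, pmin(nr, na)) == substr(alt, 1L, pmin(nr, na)))
  cls[shorter_is_prefix] <- "INDEL"
  sz[shorter_is_prefix] <- (na - nr)[shorter_is_prefix]
  data.frame(
    var_class = factor(cls, levels = c("SNP", "MNP", "INDEL", "COMPLEX")),
    indel_size = sz)
}

#' Read and filter variants from a VCF
#'
#' Retains only records with `QUAL > min_quality` and `DP > min_depth`
#' (strict inequalities). Multi-allelic records are split into one row per
#' ALT allele before filtering and classification. Records without an
#' INFO `DP` field are dropped with a warning.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param min_quality Quality threshold (exclusive). Default 20.
#' @param min_depth Depth threshold (exclusive). Default 5.
#' @return `data.frame` with columns `seq_id`, `pos` (1-based position of
#'   the REF anchor), `ref`, `alt`, `quality`, `depth`, `var_class`,
#'   `indel_size`.
#' @export
read_variants <- function(path, min_quality = 20, min_depth = 5) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  no_dp <- is.na(dp)
  if (any(no_dp))
    warning(sum(no_dp), " VCF record(s) without DP dropped")
  keep <- !no_dp & !is.na(qual) & qual > min_quality & dp > min_depth
  fix <- fix[keep, , drop = FALSE]
  dp <- dp[keep]; qual <- qual[keep]
  if (nrow(fix) == 0) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      quality = numeric(0), depth = integer(0),
                      var_class = factor(character(0),
                        levels = c("SNP", "MNP", "INDEL", "COMPLEX")),
                      indel_size = integer(0)))
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  out <- data.frame(
    seq_id = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = unlist(alts),
    quality = qual[idx],
    depth = dp[idx],
    row.names = NULL)
  cbind(out, classify_variant(out$ref, out$alt))
}

#' Write variants to a minimal VCF
#'
#' Used by the simulator; emits VCF 4.2 with QUAL and INFO `DP` only.
#'
#' @param variants `data.frame` with `seq_id`, `pos`, `ref`, `alt`,
#'   `quality`, `depth`.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gadarch",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(contigs))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contigs), unname(contigs)))
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(variants$seq_id, variants$pos)
  v <- variants[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\tDP=%d",
                  v$seq_id, v$pos, v$ref, v$alt, v$quality, v$depth)
  writeLines(c(header, body), path)
  invisible(path)
}
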
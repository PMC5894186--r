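# Independent brute-force oracles used to validate the implementation.
# These deliberately use different algorithms (per-position extension
# loops, direct codon lookup, stats::fisher.test) from the package code.

# Maximal perfect tandem arrays by per-position extension.
oracle_strs <- function(s, min_unit = 1L, max_unit = 10L,
                        th = str_default_thresholds()) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  acgt <- c("A", "C", "G", "T")
  res <- list()
  for (u in min_unit:max_unit) {
    i <- 1L
    while (i + u - 1L <= n) {
      if (!all(ch[i:(i + u - 1L)] %in% acgt)) { i <- i + 1L; next }
      # skip starts that are not left-maximal
      if (i > 1L && i - 1L + u <= n && ch[i - 1L] %in% acgt &&
          ch[i - 1L] == ch[i - 1L + u]) { i <- i + 1L; next }
      j <- i + u - 1L
      while (j + 1L <= n && ch[j + 1L] %in% acgt &&
             ch[j + 1L] == ch[j + 1L - u]) j <- j + 1L
      len <- j - i + 1L
      if (len >= th$min_len[[as.character(u)]] &&
          len / u >= th$min_copies[[as.character(u)]]) {
        minimal <- TRUE
        if (u > 1L) {
          for (q in 1:(u - 1L)) {
            if (all(ch[i:(j - q)] == ch[(i + q):j])) { minimal <- FALSE; break }
          }
        }
        if (minimal)
          res[[length(res) + 1L]] <- data.frame(start = i, end = j,
                                                unit_size = u)
      }
      i <- i + 1L
    }
  }
  if (length(res) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      unit_size = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$unit_size), , drop = FALSE]
}

str_key <- function(d) {
  if (inherits(d, "GRanges"))
    d <- data.frame(start = BiocGenerics::start(d),
                    end = BiocGenerics::end(d), unit_size = d$unit_size)
  sort(paste(d$start, d$end, d$unit_size))
}

# Per-codon translation using the genetic-code table directly.
oracle_translate <- function(s, frame) {
  if (frame < 0) {
    s <- chartr("ACGT", "TGCA",
                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    frame <- -frame
  }
  s <- substr(s, frame, nchar(s))
  n_cod <- nchar(s) %/% 3L
  if (n_cod == 0) return("")
  codons <- substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Rule-by-rule variant classification, written independently.
oracle_classify <- function(ref, alt) {
  if (nchar(ref) == nchar(alt)) {
    if (nchar(ref) == 1) return(list(cls = "SNP", size = 0L))
    return(list(cls = "MNP", size = 0L))
  }
  short <- if (nchar(ref) < nchar(alt)) ref else alt
  long <- if (nchar(ref) < nchar(alt)) alt else ref
  if (startsWith(long, short))
    return(list(cls = "INDEL", size = nchar(alt) - nchar(ref)))
  list(cls = "COMPLEX", size = 0L)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
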
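# Amino-acid alphabet used by profiles: 20 residues plus the stop symbol.
PROFILE_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")

#' Build a domain profile from a consensus protein
#'
#' An ungapped position-specific scoring matrix over the 20 amino acids
#' plus stop: the consensus residue scores `match`, every other residue
#' `mismatch`, and `*` scores `stop` (heavily penalized so hits can span
#' stop codons and be flagged rather than silently truncated). Residues
#' outside the alphabet (`X`) contribute 0.
#'
#' @param name Profile name.
#' @param consensus Consensus protein string (no stops).
#' @param match,mismatch,stop Per-column log-odds scores in bits
#'   (defaults +3, -1, -8).
#' @param bit_threshold Minimum total score for a reported hit; default
#'   `0.4 * match * nchar(consensus)` (a perfect match over 40% of the
#'   columns clears it, so >=50%-coverage copies are detectable).
#' @return A `domain_profile` object.
#' @export
domain_profile <- function(name, consensus, match = 3, mismatch = -1,
                           stop = -8,
                           bit_threshold = 0.4 * match * nchar(consensus)) {
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  if (L < 10) stop("profile length must be >= 10 columns")
  cons <- strsplit(consensus, "")[[1]]
  if (!all(cons %in% PROFILE_ALPHABET[1:20]))
    stop("consensus must use the 20 amino-acid alphabet")
  scores <- matrix(mismatch, nrow = 21, ncol = L,
                   dimnames = list(PROFILE_ALPHABET, NULL))
  scores["*", ] <- stop
  scores[cbind(match(cons, PROFILE_ALPHABET), seq_len(L))] <- match
  structure(list(name = name, length = L, scores = scores,
                 bit_threshold = bit_threshold, consensus = consensus),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("domain_profile", x$name, ":", x$length, "columns, bit_threshold",
      x$bit_threshold, "\n")
  invisible(x)
}

#' Write domain profiles to a plain-text file
#'
#' Format per profile: a header line
#' `>name<TAB>L<TAB>bit_threshold<TAB>consensus`, then `L` rows of 21
#' tab-separated log-odds scores (columns in [PROFILE_ALPHABET] order:
#' 20 amino acids then stop).
#'
#' @param profiles List of `domain_profile` objects.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(sprintf(">%s\t%d\t%.4f\t%s", p$name, p$length,
                       p$bit_threshold, p$consensus), con)
    utils::write.table(t(p$scores), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read domain profiles from a plain-text file
#'
#' @param path Path written by [write_profiles()].
#' @return Named list of `domain_profile` objects.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no profile headers in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^>", "", lines[heads[i]]), "\t")[[1]]
    L <- as.integer(hdr[2])
    block <- lines[(heads[i] + 1L):(heads[i] + L)]
    scores <- t(vapply(strsplit(block, "\t"), as.numeric, numeric(21)))
    scores <- t(scores)  # 21 x L
    rownames(scores) <- PROFILE_ALPHABET
    p <- structure(list(name = hdr[1], length = L, scores = scores,
                        bit_threshold = as.numeric(hdr[3]),
                        consensus = hdr[4]),
                   class = "domain_profile")
    out[[p$name]] <- p
  }
  out
}

#' Scan a protein string with an ungapped profile
#'
#' Every alignment offset is scored (the profile may overhang either end);
#' hits above the profile's bit threshold are reported after greedy
#' best-score-first selection of non-overlapping spans. Coverage is the
#' fraction of profile columns aligned on-sequence; `has_internal_stop`
#' flags a `*` inside the aligned span.
#'
#' @param protein Protein string (may contain `*` and `X`).
#' @param profile A `domain_profile`.
#' @return `data.frame` with `start`, `end` (1-based protein coordinates
#'   of the aligned span), `coverage`, `score`, `has_internal_stop`.
#' @export
profile_scan <- function(protein, profile) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      coverage = numeric(0), score = numeric(0),
                      has_internal_stop = logical(0))
  n <- nchar(protein)
  L <- profile$length
  if (n == 0) return(empty)
  q <- match(strsplit(protein, "")[[1]], PROFILE_ALPHABET)  # NA for X etc.
  S <- rbind(profile$scores, 0)                             # row 22: unknown
  q[is.na(q)] <- 22L
  # score for offset o = t - L (profile column j aligns protein o + j):
  # accumulate shifted score rows; t runs 1 .. n + L - 1
  sc <- numeric(n + L - 1L)
  for (j in seq_len(L)) {
    sc[seq_len(n) + (L - j)] <- sc[seq_len(n) + (L - j)] + S[q, j]
  }
  t_idx <- seq_along(sc)
  o <- t_idx - L
  span_start <- pmax(1L, o + 1L)
  span_end <- pmin(n, o + L)
  cov <- (span_end - span_start + 1L) / L
  pass <- which(sc > profile$bit_threshold)
  if (length(pass) == 0) return(empty)
  pass <- pass[order(sc[pass], decreasing = TRUE)]
  kept <- integer(0)
  for (t in pass) {
    if (length(kept) == 0 ||
        all(span_start[t] > span_end[kept] | span_end[t] < span_start[kept]))
      kept <- c(kept, t)
  }
  kept <- kept[order(span_start[kept])]
  stops <- which(q == 21L)
  has_stop <- vapply(kept, function(t)
    any(stops >= span_start[t] & stops <= span_end[t]), logical(1))
  data.frame(start = span_start[kept], end = span_end[kept],
             coverage = cov[kept], score = sc[kept],
             has_internal_stop = has_stop)
}
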
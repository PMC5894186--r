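#' Six-frame conceptual translation
#'
#' Translates a nucleotide sequence in all three frames of both strands
#' using the standard genetic code. Stop codons are rendered `*` and
#' translation continues through them; codons containing `N` (or any
#' ambiguity) become `X`; trailing partial codons are dropped. Frames
#' `-1..-3` read the reverse complement.
#'
#' @param seq A `DNAString`, `DNAStringSet` of length 1, or character
#'   scalar.
#' @return Named character vector of 6 protein strings
#'   (`+1,+2,+3,-1,-2,-3`); empty strings (with a warning) when the
#'   sequence is shorter than 3 bp.
#' @export
six_frame_translate <- function(seq) {
  if (inherits(seq, "DNAStringSet")) seq <- seq[[1]]
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  n <- length(seq)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (n < 3) {
    warning("sequence shorter than 3 bp: empty translations")
    return(stats::setNames(rep("", 6), frames))
  }
  rc <- Biostrings::reverseComplement(seq)
  one <- function(s, off) {
    len <- length(s) - off + 1L
    len <- (len %/% 3L) * 3L
    if (len < 3) return("")
    sub <- Biostrings::subseq(s, off, off + len - 1L)
    as.character(suppressWarnings(
      Biostrings::translate(sub, if.fuzzy.codon = "X")))
  }
  stats::setNames(
    c(one(seq, 1L), one(seq, 2L), one(seq, 3L),
      one(rc, 1L), one(rc, 2L), one(rc, 3L)),
    frames)
}

# Map a protein-coordinate interval [p1, p2] (1-based, inclusive) in a
# given frame back to genomic coordinates on a sequence of length n.
.backproject <- function(p1, p2, frame, n) {
  k <- abs(frame)
  g1 <- k + 3L * (p1 - 1L)
  g2 <- k + 3L * p2 - 1L
  if (frame > 0) c(g1, g2) else c(n - g2 + 1L, n - g1 + 1L)
}
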
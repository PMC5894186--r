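#' Read a genome assembly from FASTA
#'
#' Loads sequences as an uppercase [Biostrings::DNAStringSet]. Characters
#' outside `{A,C,G,T,N}` are replaced by `N` (a single warning reports how
#' many were replaced). Sequence identifiers are the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`; names are sequence identifiers.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no sequences in FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chr <- toupper(as.character(seqs))
  n_bad <- sum(vapply(chr, function(s) {
    sum(charToRaw(s) %in% charToRaw("ACGTN") == FALSE)
  }, integer(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN characters replaced by N")
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  out <- Biostrings::DNAStringSet(unname(chr))
  names(out) <- names(seqs)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_assembly <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a placed/unplaced sidecar map
#'
#' Two-column TSV with header `seq_id<TAB>placed`; `placed` is TRUE/FALSE
#' (whether the sequence is assigned to a linkage group or chromosome).
#'
#' @param path Path to the TSV.
#' @return Named logical vector keyed by `seq_id`.
#' @export
read_placed_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "logical"))
  stats::setNames(tab$placed, tab$seq_id)
}

#' Write a placed/unplaced sidecar map
#' @param placed Named logical vector.
#' @param path Output path.
#' @export
write_placed_map <- function(placed, path) {
  utils::write.table(
    data.frame(seq_id = names(placed), placed = unname(placed)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-to-GO-term associations
#'
#' TSV with header `gene_id<TAB>go_id`, one association per line. Genes may
#' appear on several lines (one per term) and terms on several lines.
#'
#' @param path Path to the TSV.
#' @return Named list: `gene_id` -> character vector of GO identifiers.
#' @export
read_go_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  split(tab$go_id, tab$gene_id)
}

#' Write gene-to-GO-term associations
#' @param go_map Named list, `gene_id` -> character vector of GO ids.
#' @param path Output path.
#' @export
write_go_map <- function(go_map, path) {
  tab <- data.frame(
    gene_id = rep(names(go_map), lengths(go_map)),
    go_id = unlist(go_map, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
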
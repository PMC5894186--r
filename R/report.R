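#' Long-format domain census table
#'
#' Reshapes a [census()] report into the familiar copy-number-proxy
#' layout: one row per profile and bin (`all`, `>50%`, `>75%`,
#' `>75% with stops`).
#'
#' @param report The `report` element of a [census()] result.
#' @return `data.frame` with columns `profile`, `bin`, `n`.
#' @export
report_census_table <- function(report) {
  bins <- c(n_all = "all", n_gt50 = ">50% domain length",
            n_gt75 = ">75% domain length",
            n_gt75_with_stops = ">75% domain length, with stop codons")
  out <- do.call(rbind, lapply(seq_len(nrow(report)), function(i)
    data.frame(profile = report$profile[i], bin = unname(bins),
               n = as.integer(report[i, names(bins)]))))
  out
}

#' Term-by-species-pair significance matrix
#'
#' Presence/absence matrix of significant between-species differences:
#' rows are GO terms, columns are species pairs.
#'
#' @param tests The `tests` element of a [pairwise_species_tests()] result.
#' @return Logical matrix, terms x pairs.
#' @export
report_significance_matrix <- function(tests) {
  pair <- paste(tests$species_a, tests$species_b, sep = ":")
  terms <- sort(unique(tests$go_id))
  pairs <- sort(unique(pair))
  m <- matrix(FALSE, length(terms), length(pairs),
              dimnames = list(terms, pairs))
  m[cbind(match(tests$go_id, terms), match(pair, pairs))] <-
    tests$significant
  m
}

#' Write a data frame as TSV
#'
#' Convenience wrapper used by the analysis drivers: tab separated, no
#' quoting, no row names.
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
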
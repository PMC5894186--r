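#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computed by exhaustive enumeration of the hypergeometric support at the
#' observed margins: the two-sided p-value is the sum of point
#' probabilities of all tables whose probability does not exceed that of
#' the observed table (within relative tolerance `1e-7` for ties). The
#' direction is read from the sample odds ratio: `enriched` when
#' `ad > bc`, `purified` when `ad < bc`, `none` otherwise.
#'
#' @param tab 2x2 matrix of nonnegative counts, rows = groups, columns =
#'   with/without.
#' @return List with `p_value`, `odds_ratio` (sample `ad/bc`, `NA` when
#'   `bc == 0` and `ad > 0`, etc.), and `direction`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("tab must contain nonnegative integers")
  if (sum(tab) == 0) stop("all-zero table: test undefined")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c          # column-1 margin ("with")
  n_ <- b + d         # column-2 margin
  k <- a + b          # row-1 margin
  lo <- max(0L, k - n_); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_, k)
  obs <- probs[support == a]
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  p <- min(1, p)
  ad <- a * d; bc <- b * c
  or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  direction <- if (is.nan(or)) "none" else if (or > 1) "enriched" else
    if (or < 1) "purified" else "none"
  list(p_value = p, odds_ratio = or, direction = direction)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Adjusted p-values are
#' `min(1, min_{j >= rank} p_(j) * m * c(m) / j)` with
#' `c(m) = sum_{i=1..m} 1/i`, valid under arbitrary dependence between
#' tests.
#'
#' @param raw_p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Rejection level (default 0.05).
#' @return List with `m`, `raw_p`, `adjusted_p`, `rejected`
#'   (`adjusted_p <= alpha`), and `method = "BY"`.
#' @export
by_fdr <- function(raw_p, alpha = 0.05) {
  if (any(is.na(raw_p)) || any(raw_p < 0 | raw_p > 1))
    stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(raw_p, method = "BY")
  list(m = length(raw_p), raw_p = raw_p, adjusted_p = adj,
       rejected = adj <= alpha, method = "BY")
}

#' Per-term with/without-STR counts for one species
#'
#' Builds the Gene Ontology count table Fisher tests consume: for every
#' term, the number of annotated genes carrying at least one STR and the
#' number without, plus the species-wide background.
#'
#' @param go_map Named list `gene_id` -> GO ids (from [read_go_map()] or
#'   [attach_go_terms()] models' `go` slot).
#' @param str_flags Named logical vector `gene_id` -> has STR (e.g.
#'   `setNames(summary$has_str, summary$gene_id)` from
#'   [genes_with_strs()]).
#' @return `data.frame` with columns `go_id`, `n_with`, `n_without`, plus
#'   attributes `bg_with` / `bg_without` (species background).
#' @export
go_count_table <- function(go_map, str_flags) {
  go_map <- go_map[lengths(go_map) > 0]
  genes <- rep(names(go_map), lengths(go_map))
  terms <- unlist(go_map, use.names = FALSE)
  flag <- str_flags[genes]
  flag[is.na(flag)] <- FALSE
  agg <- tapply(flag, terms, function(f) c(sum(f), sum(!f)))
  out <- data.frame(go_id = names(agg),
                    n_with = vapply(agg, `[`, numeric(1), 1),
                    n_without = vapply(agg, `[`, numeric(1), 2),
                    row.names = NULL)
  bg_genes <- unique(genes)
  attr(out, "bg_with") <- sum(str_flags[bg_genes], na.rm = TRUE)
  attr(out, "bg_without") <- sum(!str_flags[bg_genes], na.rm = TRUE)
  out
}

#' Between-species pairwise STR-enrichment tests per GO term
#'
#' For every GO term and unordered species pair, Fisher's exact test on
#' `[[A_with, A_without], [B_with, B_without]]`. FDR is pooled over all
#' term-by-pair tests with Benjamini-Yekutieli; a term is significant when
#' any of its pairwise tests survives at `alpha`.
#'
#' @param tables Named list of per-species count tables from
#'   [go_count_table()].
#' @param alpha FDR level (default 0.05).
#' @return List with `tests` (long `data.frame`: `go_id`, `species_a`,
#'   `species_b`, the four cells, `p_value`, `adjusted_p`, `significant`,
#'   `direction`), `significant_terms` (character), and `fdr` (the pooled
#'   [by_fdr()] result).
#' @export
pairwise_species_tests <- function(tables, alpha = 0.05) {
  if (length(tables) < 2) stop("need at least two species")
  sp <- names(tables)
  lk <- lapply(tables, function(t) {
    m <- cbind(with = t$n_with, without = t$n_without)
    rownames(m) <- t$go_id
    m
  })
  pairs <- utils::combn(sp, 2, simplify = FALSE)
  rows <- list()
  skipped <- 0L
  for (pr in pairs) {
    a <- lk[[pr[1]]]; b <- lk[[pr[2]]]
    shared <- intersect(rownames(a), rownames(b))
    only <- setdiff(union(rownames(a), rownames(b)), shared)
    skipped <- skipped + length(only)
    for (term in shared) {
      tab <- rbind(a[term, ], b[term, ])
      if (sum(tab) == 0) next
      ft <- fisher_exact_2x2(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        go_id = term, species_a = pr[1], species_b = pr[2],
        a_with = tab[1, 1], a_without = tab[1, 2],
        b_with = tab[2, 1], b_without = tab[2, 2],
        p_value = ft$p_value, direction = ft$direction)
    }
  }
  if (skipped > 0)
    warning(skipped, " term/species-pair combination(s) skipped: term ",
            "absent in one species")
  tests <- do.call(rbind, rows)
  fdr <- by_fdr(tests$p_value, alpha)
  tests$adjusted_p <- fdr$adjusted_p
  tests$significant <- fdr$rejected
  list(tests = tests,
       significant_terms = sort(unique(tests$go_id[tests$significant])),
       fdr = fdr)
}

#' Within-species STR enrichment/purification per GO term
#'
#' For every term, Fisher's exact test on
#' `[[in-term with, in-term without], [out-of-term with, out-of-term
#' without]]` against the species background; direction from the odds
#' ratio (`enriched` = more STR-carrying genes than expected, `purified` =
#' fewer). Benjamini-Yekutieli corrected.
#'
#' @param go_map Named list `gene_id` -> GO ids.
#' @param str_flags Named logical `gene_id` -> has STR. To stratify by
#'   unit size (e.g. trinucleotide only), pass flags computed from loci of
#'   that unit size.
#' @param alpha FDR level for the `rejected` column (default 0.05).
#' @param alpha_display Display threshold echoed in the `displayed` column
#'   (default 0.01).
#' @return `data.frame`: `go_id`, the four cells, `p_value`, `direction`,
#'   `adjusted_p`, `rejected`, `displayed`.
#' @export
within_species_enrichment <- function(go_map, str_flags, alpha = 0.05,
                                      alpha_display = 0.01) {
  ct <- go_count_table(go_map, str_flags)
  annotated <- unique(rep(names(go_map), lengths(go_map)))
  tot_with <- sum(str_flags[annotated], na.rm = TRUE)
  tot_without <- sum(!str_flags[annotated], na.rm = TRUE)
  rows <- lapply(seq_len(nrow(ct)), function(i) {
    tab <- rbind(c(ct$n_with[i], ct$n_without[i]),
                 c(tot_with - ct$n_with[i], tot_without - ct$n_without[i]))
    ft <- fisher_exact_2x2(tab)
    data.frame(go_id = ct$go_id[i],
               term_with = tab[1, 1], term_without = tab[1, 2],
               rest_with = tab[2, 1], rest_without = tab[2, 2],
               p_value = ft$p_value, direction = ft$direction)
  })
  out <- do.call(rbind, rows)
  fdr <- by_fdr(out$p_value, alpha)
  out$adjusted_p <- fdr$adjusted_p
  out$rejected <- fdr$rejected
  out$displayed <- out$adjusted_p <= alpha_display
  out
}
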
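test_that("fisher two-sided p matches stats::fisher.test exhaustively", {
  # hand-derivable cases
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")

  # exhaustive over all tables with total n <= 12
  grid <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  grid <- grid[rowSums(grid) > 0 & rowSums(grid) <= 12, ]
  p_got <- numeric(nrow(grid)); p_ref <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tab <- matrix(as.numeric(grid[i, ]), 2, byrow = TRUE)
    p_got[i] <- fisher_exact_2x2(tab)$p_value
    p_ref[i] <- stats::fisher.test(tab)$p.value
  }
  expect_equal(p_got, p_ref, tolerance = 1e-10)
})

test_that("fisher p matches reference on random tables up to n = 40", {
  set.seed(501)
  for (k in 1:400) {
    repeat {
      tab <- matrix(stats::rmultinom(1, sample(1:40, 1), rep(0.25, 4)), 2)
      if (sum(tab) > 0) break
    }
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("fisher direction follows the odds ratio and survives transpose", {
  expect_equal(fisher_exact_2x2(rbind(c(9, 1), c(2, 8)))$direction,
               "enriched")
  expect_equal(fisher_exact_2x2(rbind(c(1, 9), c(8, 2)))$direction,
               "purified")
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$direction, "none")
  set.seed(502)
  for (k in 1:100) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
  }
})

test_that("BY adjustment: hand-computed cases, BH dominance, monotonicity", {
  expect_equal(by_fdr(0.04)$adjusted_p, 0.04)           # c(1) = 1
  # m = 3, c(3) = 11/6: all three adjust to 0.01 * 3 * 11/6 = 0.055
  r <- by_fdr(c(0.01, 0.02, 0.03))
  expect_equal(r$adjusted_p, rep(0.055, 3), tolerance = 1e-12)
  expect_equal(r$m, 3)

  set.seed(503)
  for (k in 1:20) {
    p <- stats::runif(sample(2:200, 1))
    adj <- by_fdr(p)$adjusted_p
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(adj >= stats::p.adjust(p, "BH") - 1e-15))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
  }
  expect_error(by_fdr(c(0.5, 1.2)), "p-values")
})

test_that("go_count_table tallies with/without per term and background", {
  go_map <- list(g1 = c("T1", "T2"), g2 = "T1", g3 = "T2", g4 = "T1")
  flags <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = FALSE)
  ct <- go_count_table(go_map, flags)
  expect_equal(ct$n_with[ct$go_id == "T1"], 1)
  expect_equal(ct$n_without[ct$go_id == "T1"], 2)
  expect_equal(ct$n_with[ct$go_id == "T2"], 2)
  expect_equal(attr(ct, "bg_with"), 2)
  expect_equal(attr(ct, "bg_without"), 2)
})

test_that("pairwise tests: identical proportions yield no significance", {
  tab <- data.frame(go_id = sprintf("T%02d", 1:20),
                    n_with = rep(30, 20), n_without = rep(70, 20))
  res <- pairwise_species_tests(list(A = tab, B = tab, C = tab))
  expect_equal(length(res$significant_terms), 0)
  expect_true(all(res$tests$p_value > 1 - 1e-9))
})

test_that("pairwise tests reproduce the two-against-one block pattern", {
  # species A and C share a high STR proportion in T1, species B does not
  base <- data.frame(go_id = c("T1", "T2"), n_with = c(100, 50),
                     n_without = c(100, 150))
  b <- data.frame(go_id = c("T1", "T2"), n_with = c(30, 50),
                  n_without = c(170, 150))
  res <- pairwise_species_tests(list(A = base, B = b, C = base))
  t1 <- res$tests[res$tests$go_id == "T1", ]
  sig_pairs <- paste(t1$species_a, t1$species_b)[t1$significant]
  expect_setequal(sig_pairs, c("A B", "B C"))
  expect_false("A C" %in% sig_pairs)
  expect_true("T1" %in% res$significant_terms)
  expect_false("T2" %in% res$significant_terms)
})

test_that("pairwise tests skip terms missing in one species with a warning", {
  a <- data.frame(go_id = c("T1", "T2"), n_with = c(10, 10),
                  n_without = c(10, 10))
  b <- data.frame(go_id = "T1", n_with = 10, n_without = 10)
  expect_warning(res <- pairwise_species_tests(list(A = a, B = b)),
                 "skipped")
  expect_equal(nrow(res$tests), 1)
  expect_error(pairwise_species_tests(list(A = a)), "two species")
})

test_that("within-species enrichment recovers planted directions", {
  # term whose genes all carry STRs against a 50% background
  go_map <- c(lapply(stats::setNames(sprintf("e%02d", 1:20),
                                     sprintf("e%02d", 1:20)),
                     function(g) "T_enr"),
              lapply(stats::setNames(sprintf("b%03d", 1:200),
                                     sprintf("b%03d", 1:200)),
                     function(g) "T_bg"))
  flags <- c(stats::setNames(rep(TRUE, 20), sprintf("e%02d", 1:20)),
             stats::setNames(rep(c(TRUE, FALSE), 100),
                             sprintf("b%03d", 1:200)))
  res <- within_species_enrichment(go_map, flags)
  enr <- res[res$go_id == "T_enr", ]
  expect_equal(enr$direction, "enriched")
  expect_true(enr$rejected)

  # a term at exactly the background proportion: p = 1, no direction
  neutral <- c(lapply(stats::setNames(sprintf("n%03d", 1:100),
                                      sprintf("n%03d", 1:100)),
                      function(g) "T_a"),
               lapply(stats::setNames(sprintf("m%03d", 1:200),
                                      sprintf("m%03d", 1:200)),
                      function(g) "T_b"))
  nflags <- c(stats::setNames(rep(c(TRUE, FALSE), 50),
                              sprintf("n%03d", 1:100)),
              stats::setNames(rep(c(TRUE, FALSE), 100),
                              sprintf("m%03d", 1:200)))
  rn <- within_species_enrichment(neutral, nflags)
  expect_true(all(rn$p_value > 1 - 1e-9))
  expect_true(all(rn$direction == "none"))

  # purified term: no STR-carrying genes at all
  go_map$p01 <- "T_pur"; go_map$p02 <- "T_pur"
  go_map <- c(go_map, lapply(stats::setNames(sprintf("p%02d", 3:30),
                                             sprintf("p%02d", 3:30)),
                             function(g) "T_pur"))
  flags <- c(flags, stats::setNames(rep(FALSE, 30), sprintf("p%02d", 1:30)))
  res2 <- within_species_enrichment(go_map, flags)
  pur <- res2[res2$go_id == "T_pur", ]
  expect_equal(pur$direction, "purified")
})

test_that("null data keep the BY false-positive rate at or below alpha", {
  set.seed(504)
  fp <- replicate(40, {
    tabs <- simulate_go_counts(n_terms = 100, genes_per_term = 50,
                               base_p = 0.2)
    res <- suppressWarnings(pairwise_species_tests(tabs, alpha = 0.05))
    length(res$significant_terms) / 100
  })
  expect_lte(mean(fp), 0.05)
})

test_that("BH rejects at least as often as BY on the same p-values", {
  set.seed(505)
  p <- c(stats::runif(450), stats::rbeta(50, 0.1, 1))
  by_rej <- sum(by_fdr(p)$rejected)
  bh_rej <- sum(stats::p.adjust(p, "BH") <= 0.05)
  expect_gte(bh_rej, by_rej)
})

test_that("permuting gene STR flags destroys planted signal", {
  set.seed(506)
  genes <- sprintf("g%04d", 1:2000)
  go_map <- stats::setNames(
    lapply(genes, function(g) sprintf("T%02d", sample(40, 2))), genes)
  flags <- stats::setNames(stats::runif(2000) < 0.3, genes)
  # plant: genes in T01 almost always carry STRs
  in_t1 <- vapply(go_map, function(tt) "T01" %in% tt, logical(1))
  flags[in_t1] <- stats::runif(sum(in_t1)) < 0.9
  res <- within_species_enrichment(go_map, flags)
  expect_true(res$rejected[res$go_id == "T01"])

  perm <- stats::setNames(sample(flags), names(flags))
  res_perm <- within_species_enrichment(go_map, perm)
  expect_equal(sum(res_perm$rejected), 0)
  ks <- suppressWarnings(stats::ks.test(res_perm$p_value, "punif"))
  expect_gt(ks$p.value, 1e-3)
})
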
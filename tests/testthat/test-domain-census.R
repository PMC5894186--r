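test_that("six-frame translation: codon cases and per-codon oracle", {
  expect_equal(six_frame_translate("ATGAAATAA")[["+1"]], "MK*")
  expect_equal(six_frame_translate("ATGAAA")[["-1"]], "FH")  # rc = TTTCAT
  expect_equal(six_frame_translate("ATGNNNAAA")[["+1"]], "MXK")
  expect_warning(fr <- six_frame_translate("AT"), "shorter than 3")
  expect_true(all(fr == ""))

  set.seed(601)
  s <- random_dna(999)
  fr <- six_frame_translate(s)
  for (f in c(1, 2, 3, -1, -2, -3))
    expect_equal(fr[[sprintf("%+d", f)]], oracle_translate(s, f))
})

test_that("profile scan: consensus, truncation and stop flagging", {
  set.seed(602)
  p <- domain_profile("dom", gadarch:::.random_consensus(50))
  hit <- profile_scan(p$consensus, p)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$coverage, 1.0)
  expect_equal(hit$score, 3 * 50)            # every column matches
  expect_false(hit$has_internal_stop)

  # 60% truncation: coverage 0.60, counted >50% but not >75%
  trunc <- substr(p$consensus, 1, 30)
  h2 <- profile_scan(trunc, p)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$coverage, 0.60)
  expect_true(h2$coverage > 0.5 && h2$coverage <= 0.75)

  # internal stop is spanned and flagged
  withstop <- paste0(substr(p$consensus, 1, 24), "*",
                     substr(p$consensus, 26, 50))
  h3 <- profile_scan(withstop, p)
  expect_equal(nrow(h3), 1)
  expect_true(h3$has_internal_stop)
  expect_equal(h3$score, 3 * 49 - 8)

  expect_equal(nrow(profile_scan("", p)), 0)
})

test_that("profile files round-trip", {
  set.seed(603)
  p1 <- domain_profile("alpha", gadarch:::.random_consensus(30))
  p2 <- domain_profile("beta", gadarch:::.random_consensus(45),
                       bit_threshold = 22.5)
  path <- file.path(tempdir(), "profiles_rt.txt")
  write_profiles(list(p1, p2), path)
  back <- read_profiles(path)
  expect_equal(names(back), c("alpha", "beta"))
  expect_equal(back$alpha$scores, p1$scores,
               ignore_attr = FALSE, tolerance = 1e-9)
  expect_equal(back$beta$bit_threshold, 22.5)
  expect_equal(back$beta$consensus, p2$consensus)
})

test_that("census recovers planted copies with bins, stops and dedup", {
  sim <- small_sim()
  cen <- census(small_assembly(), sim$truth$profiles,
                read_placed_map(sim$files[["placed"]]))
  rep_a <- cen$report[cen$report$profile == "fam_a", ]
  truth <- sim$truth$domains
  # 6 copies, one contig collapsed x2 -> 5 emitted loci
  expect_equal(rep_a$n_all, nrow(truth))
  expect_equal(rep_a$n_gt75, nrow(truth))
  expect_equal(rep_a$n_gt75_with_stops, sum(truth$pseudo))
  # bin nesting and placed split
  expect_lte(rep_a$n_gt75, rep_a$n_gt50)
  expect_lte(rep_a$n_gt50, rep_a$n_all)
  expect_equal(rep_a$n_placed + rep_a$n_unplaced, rep_a$n_all)
  expect_equal(rep_a$n_unplaced, nrow(truth))   # domain contigs unplaced
  # every hit back-projects onto a planted copy
  hits <- cen$hits
  m <- merge(hits, truth, by = "seq_id")
  expect_true(all(m$g_start >= m$start - 3 & m$g_end <= m$end + 3))
})

test_that("tandem copies on one contig dedup per copy, not per frame", {
  set.seed(604)
  p <- domain_profile("tand", gadarch:::.random_consensus(40))
  aa <- strsplit(p$consensus, "")[[1]]
  one <- gadarch:::.reverse_translate(aa)
  spacer <- function() sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  contig <- paste(c(spacer(),
                    unlist(lapply(1:5, function(i) c(one, spacer())))),
                  collapse = "")
  asm <- Biostrings::DNAStringSet(c(tandem = contig))
  cen <- census(asm, list(p))
  expect_equal(cen$report$n_all, 5)
  expect_gte(cen$report$n_raw, 5)
  # dedup idempotence: re-deduplicating the deduped hits changes nothing
  expect_identical(gadarch:::.dedup_hits(cen$hits[, names(cen$raw_hits)]),
                   cen$hits[, names(cen$raw_hits)])
})

test_that("census is reverse-complement symmetric and handles empties", {
  set.seed(605)
  p <- domain_profile("sym", gadarch:::.random_consensus(35))
  dna <- paste(c(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 gadarch:::.reverse_translate(strsplit(p$consensus, "")[[1]]),
                 sample(c("A", "C", "G", "T"), 50, replace = TRUE)),
               collapse = "")
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
  c1 <- census(Biostrings::DNAStringSet(c(x = dna)), list(p))
  c2 <- census(Biostrings::DNAStringSet(c(x = rc)), list(p))
  expect_equal(c1$report$n_all, c2$report$n_all)
  expect_equal(c1$report$n_gt75, c2$report$n_gt75)
  expect_equal(sort(c1$hits$g_start),
               sort(nchar(dna) - c2$hits$g_end + 1))

  c0 <- census(Biostrings::DNAStringSet(), list(p))
  expect_equal(c0$report$n_all, 0)
  expect_equal(c0$report$n_gt75_with_stops, 0)

  # unknown seq in placed map handled as unplaced with warning
  expect_warning(
    cw <- census(Biostrings::DNAStringSet(c(x = dna)), list(p),
                 placed_map = c(other = TRUE)),
    "absent from placed map")
  expect_equal(cw$report$n_unplaced, cw$report$n_all)
})

test_that("copy completeness bounds are inclusive at 60% and 100%", {
  expect_equal(as.character(classify_copy_completeness(1.0)), "full_length")
  expect_equal(as.character(classify_copy_completeness(0.60)), "partial")
  expect_equal(as.character(classify_copy_completeness(0.59)), "below")
  expect_equal(as.character(classify_copy_completeness(c(0.99, 0.75))),
               c("partial", "partial"))
  expect_error(classify_copy_completeness(1.2), "coverage")
})

test_that("MHC-style region classification by alpha-domain co-occurrence", {
  hits <- data.frame(seq_id = "c1", domain = c("a1", "a2", "a3"),
                     g_start = c(1000, 2500, 4000),
                     g_end = c(1200, 2700, 4200))
  r <- classify_mhc_region(hits)
  expect_equal(nrow(r), 1)
  expect_equal(r$label, "a1+a2+a3")

  lone <- data.frame(seq_id = "c2", domain = "a3",
                     g_start = 500, g_end = 700)
  expect_equal(classify_mhc_region(lone)$label, "a3")

  # two distant clusters resolve into separate regions, greedily
  far <- rbind(hits,
               data.frame(seq_id = "c1", domain = c("a2", "a3"),
                          g_start = c(40000, 41000),
                          g_end = c(40200, 41200)))
  r2 <- classify_mhc_region(far)
  expect_equal(sort(r2$label), c("a1+a2+a3", "a2+a3"))

  # planted synthesis: 10 complete regions and 7 isolated a3 fragments
  set.seed(606)
  rows <- list()
  for (i in 1:10) {
    base <- i * 1e5
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = sprintf("r%02d", i), domain = c("a1", "a2", "a3"),
      g_start = base + c(0, 3000, 6000), g_end = base + c(200, 3200, 6200))
  }
  for (i in 1:7)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = sprintf("f%02d", i), domain = "a3",
      g_start = 100, g_end = 300)
  r3 <- classify_mhc_region(do.call(rbind, rows))
  expect_equal(sum(r3$label == "a1+a2+a3"), 10)
  expect_equal(sum(r3$label == "a3"), 7)

  expect_equal(nrow(classify_mhc_region(hits[0, ])), 0)
})
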
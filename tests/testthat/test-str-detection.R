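test_that("worked examples: thresholds, partial units, minimal period, N", {
  # (AC)x6 meets the 12 bp default floor
  g <- find_strs(c(s = "ACACACACACAC"))
  expect_equal(length(g), 1)
  expect_equal(g$unit_size, 2L)
  expect_equal(g$motif, "AC")
  expect_equal(g$copy_number, 6)
  expect_equal(BiocGenerics::start(g), 1)
  expect_equal(BiocGenerics::end(g), 12)

  # below threshold: not reported at u=2, and never at u=4 or u=6
  expect_equal(length(find_strs(c(s = "ACACAC"))), 0)

  # partial trailing unit counts: ACACA at a permissive threshold
  th <- str_default_thresholds()
  th$min_len[] <- 5; th$min_copies[] <- th$min_len / as.integer(names(th$min_len))
  g <- find_strs(c(s = "ACACA"), thresholds = th)
  expect_equal(g$copy_number[g$unit_size == 2], 2.5)

  # arrays never span N
  g <- find_strs(c(s = "AAAAAAAAAAAANAAAAAAAAAAAA"))
  expect_equal(length(g), 2)
  expect_equal(BiocGenerics::start(g), c(1, 14))

  expect_error(find_strs(c(s = "ACGT"), min_unit = 5, max_unit = 2),
               "min_unit")
})

test_that("detector equals brute-force oracle exhaustively on {A,C} strings", {
  strings <- character(0)
  for (len in c(12, 13)) {
    combos <- expand.grid(rep(list(c("A", "C")), len),
                          stringsAsFactors = FALSE)
    strings <- c(strings, do.call(paste0, combos))
  }
  names(strings) <- sprintf("q%05d", seq_along(strings))
  got <- find_strs(strings)
  got_df <- data.frame(id = as.character(GenomicRanges::seqnames(got)),
                       start = BiocGenerics::start(got),
                       end = BiocGenerics::end(got),
                       unit_size = got$unit_size)
  by_id <- split(got_df, factor(got_df$id, levels = names(strings)))
  mismatch <- 0L
  for (id in names(strings)) {
    exp_key <- str_key(oracle_strs(strings[[id]]))
    if (!identical(str_key(by_id[[id]]), exp_key)) mismatch <- mismatch + 1L
  }
  expect_equal(mismatch, 0L)
})

test_that("detector equals brute-force oracle on random 1 kbp sequences", {
  set.seed(303)
  for (rep in 1:30) {
    s <- random_dna(1000)
    # salt with tandem arrays and Ns so the oracle sees real structure
    u <- sample(1:10, 1)
    unit <- random_dna(u)
    arr <- strrep(unit, 4)
    at <- sample(900, 1)
    substr(s, at, at + nchar(arr) - 1) <- arr
    if (rep %% 3 == 0) substr(s, sample(1000, 1), 1000) <- "N"
    got <- find_strs(stats::setNames(s, "x"))
    expect_identical(str_key(got), str_key(oracle_strs(s)))
  }
})

test_that("reported loci are maximal perfect arrays", {
  set.seed(304)
  s <- random_dna(3000)
  for (k in 1:20) {
    unit <- random_dna(sample(1:6, 1))
    arr <- strrep(unit, 6)
    at <- sample(2800, 1)
    substr(s, at, at + nchar(arr) - 1) <- arr
  }
  ch <- strsplit(s, "")[[1]]
  g <- find_strs(stats::setNames(s, "x"))
  for (i in seq_along(g)) {
    st <- BiocGenerics::start(g)[i]; en <- BiocGenerics::end(g)[i]
    u <- g$unit_size[i]
    if (st > 1 && st - 1 + u <= length(ch))
      expect_false(isTRUE(ch[st - 1] == ch[st - 1 + u]))
    if (en < length(ch))
      expect_false(isTRUE(ch[en + 1] == ch[en + 1 - u]))
  }
})

test_that("canonical motifs: hand cases and exhaustive trinucleotide classes", {
  expect_equal(canonical_motif("GA"), "AG")
  expect_equal(canonical_motif("AT"), "AT")
  expect_equal(canonical_motif("TC"), "AG")   # revcomp of GA class
  expect_error(canonical_motif("AN"), "only A, C, G, T")

  tri <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 3),
                                     stringsAsFactors = FALSE))
  canon <- canonical_motif(tri)
  # independent enumeration of rotation+revcomp equivalence classes
  own_class <- lapply(tri, function(w) {
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(w, "")[[1]]), collapse = ""))
    rots <- function(x) vapply(1:3, function(i)
      paste0(substr(x, i, 3), substr(x, 1, i - 1)), character(1))
    sort(unique(c(rots(w), rots(rc))))
  })
  expect_equal(length(unique(canon)),
               length(unique(vapply(own_class, paste, character(1),
                                    collapse = ","))))
  # each motif is the lexicographic minimum of its own class
  expect_identical(canon, vapply(own_class, min, character(1)))
})

test_that("canonical motif spectrum is reverse-complement symmetric", {
  set.seed(305)
  s <- random_dna(5000)
  for (k in 1:15) {
    unit <- random_dna(sample(1:5, 1))
    arr <- strrep(unit, 8)
    at <- sample(4800, 1)
    substr(s, at, at + nchar(arr) - 1) <- arr
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  sp1 <- sort(table(find_strs(c(x = s))$motif))
  sp2 <- sort(table(find_strs(c(x = rc))$motif))
  expect_identical(sp1, sp2)
})

test_that("region clipping matches an interval-intersection oracle", {
  loci <- GenomicRanges::GRanges("c1", IRanges::IRanges(100, 129))
  loci$unit_size <- 2L; loci$motif <- "AC"
  loci$copy_number <- 15; loci$array_bp <- 30L
  cds <- GenomicRanges::GRanges("c1", IRanges::IRanges(110, 200))
  clipped <- strs_in_regions(loci, cds)
  expect_equal(BiocGenerics::start(clipped), 110)
  expect_equal(BiocGenerics::end(clipped), 129)
  expect_equal(clipped$array_bp, 20)
  expect_equal(clipped$copy_number, 10)

  # locus fully inside stays unchanged
  inside <- strs_in_regions(loci, GenomicRanges::GRanges(
    "c1", IRanges::IRanges(50, 300)))
  expect_equal(BiocGenerics::start(inside), 100)
  expect_equal(inside$array_bp, 30)

  # random loci vs a manual intersection total
  set.seed(306)
  n <- 200
  loci <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    sample(10000, n), width = sample(10:50, n, replace = TRUE)))
  loci$unit_size <- sample(1:10, n, replace = TRUE)
  loci$motif <- "A"; loci$copy_number <- 1; loci$array_bp <- BiocGenerics::width(loci)
  regions <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "c1", IRanges::IRanges(sample(10000, 30),
                           width = sample(50:400, 30, replace = TRUE))))
  clipped <- strs_in_regions(loci, regions)
  manual <- 0
  for (i in seq_along(loci)) for (j in seq_along(regions)) {
    ov <- min(BiocGenerics::end(loci)[i], BiocGenerics::end(regions)[j]) -
      max(BiocGenerics::start(loci)[i], BiocGenerics::start(regions)[j]) + 1
    if (ov > 0) manual <- manual + ov
  }
  expect_equal(sum(clipped$array_bp), manual)
})

test_that("density/frequency arithmetic and overlap-resolved conservation", {
  loci <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    seq(1, by = 100, length.out = 20), width = 25))
  loci$unit_size <- rep(c(2L, 3L), 10)
  loci$motif <- "AC"; loci$copy_number <- 1
  loci$array_bp <- BiocGenerics::width(loci)
  st <- str_statistics(loci, region_bp = 2e6)
  expect_equal(st$density[st$unit_size == "total"], 250)
  expect_equal(st$frequency[st$unit_size == "total"], 10)

  empty <- find_strs(c(s = "ACGTACGGTA"))
  st0 <- str_statistics(empty, region_bp = 1e6)
  expect_equal(st0$density[st0$unit_size == "total"], 0)
  expect_error(str_statistics(empty, region_bp = 0), "region_bp")

  # overlapping arrays of different unit size never double-count bp
  set.seed(307)
  n <- 100
  loci <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    sample(5000, n, replace = TRUE), width = sample(12:40, n, replace = TRUE)))
  loci$unit_size <- sample(1:10, n, replace = TRUE)
  loci$motif <- "A"; loci$copy_number <- 1
  loci$array_bp <- BiocGenerics::width(loci)
  st <- str_statistics(loci, region_bp = 6000)
  tot <- st$array_bp_total[st$unit_size == "total"]
  expect_lte(tot, 6000)
  expect_equal(sum(st$array_bp_total[st$unit_size != "total"]), tot)
  covered <- sum(BiocGenerics::width(GenomicRanges::reduce(loci,
                                                           ignore.strand = TRUE)))
  expect_equal(tot, covered)
})
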
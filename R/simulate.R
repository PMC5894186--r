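#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate the statistical structure the analyses assume: an STR
#' spectrum dominated by dinucleotides totalling 96,364 bp/Mbp (the
#' assembly-wide density observed in haddock), gene models carrying CDS
#' trinucleotide arrays with GO-level enrichment effects, variant classes
#' at haddock-like per-bp rates including size-3 indels planted inside
#' genic trinucleotide arrays, two multi-copy domain families with
#' pseudogenized (internal stop) members, and assembly collapse expressed
#' as one contig standing for k copies at k-fold read depth.
#'
#' @param seed Integer seed; fully determines every output.
#' @param n_contigs,contig_length Background contigs (default 6 x 300 kbp).
#' @param str_spectrum Named numeric, unit size -> target density (bp/Mbp).
#' @param n_genes Number of gene models (default 400).
#' @param exons_per_gene,exon_bp,intron_bp Gene geometry (3 x 400 bp exons,
#'   600 bp introns by default).
#' @param n_go_terms,genes_per_term GO vocabulary size and term-size range.
#' @param base_str_p Baseline per-gene probability of carrying a CDS STR.
#' @param enriched_terms Named numeric: term id -> effect multiplier on the
#'   per-gene STR probability (> 1 enriched, < 1 purified).
#' @param variant_rates Named per-bp rates (SNP, MNP, INDEL, COMPLEX).
#' @param pass_fraction Fraction of variants passing the quality/depth
#'   filter (QUAL > 20 and DP > 5).
#' @param n_tri_indel_genes Genes receiving a size-3 indel inside a genic
#'   trinucleotide array (default 12).
#' @param domain_families List of families: each
#'   `list(consensus_length=, n_copies=, pseudogene_fraction=, collapse=)`
#'   where `collapse` is a vector of multiplicities, each absorbing that
#'   many true copies into one emitted contig at multiplied read depth.
#' @param base_depth Mean per-base read depth (default 25).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 6L,
                       contig_length = 300000L,
                       str_spectrum = c(`1` = 6000, `2` = 55364, `3` = 12000,
                                        `4` = 9000, `5` = 6000, `6` = 4000,
                                        `7` = 2000, `8` = 1200, `9` = 600,
                                        `10` = 200),
                       n_genes = 400L,
                       exons_per_gene = 3L,
                       exon_bp = 400L,
                       intron_bp = 600L,
                       n_go_terms = 40L,
                       genes_per_term = c(5L, 30L),
                       base_str_p = 0.3,
                       enriched_terms = c("GO:0000001" = 3, "GO:0000002" = 3,
                                          "GO:0000003" = 3, "GO:0000004" = 3,
                                          "GO:0000005" = 0.3,
                                          "GO:0000006" = 0.3),
                       variant_rates = c(SNP = 5.4e-3, MNP = 0.2e-3,
                                         INDEL = 1.6e-3, COMPLEX = 0.5e-3),
                       pass_fraction = 0.75,
                       n_tri_indel_genes = 12L,
                       domain_families = list(
                         nacht_like = list(consensus_length = 120L,
                                           n_copies = 15L,
                                           pseudogene_fraction = 0.2,
                                           collapse = integer(0)),
                         fisna_like = list(consensus_length = 72L,
                                           n_copies = 15L,
                                           pseudogene_fraction = 0.2,
                                           collapse = c(2L, 3L, 5L))),
                       base_depth = 25) {
  if (any(str_spectrum < 0) || any(str_spectrum > 1e6))
    stop("densities must be in [0, 1e6] bp/Mbp")
  if (base_str_p < 0 || base_str_p > 1) stop("base_str_p must be in [0,1]")
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

.random_dna_chars <- function(n) sample(BASES, n, replace = TRUE)

# smallest period of a character vector
.min_period <- function(ch) {
  n <- length(ch)
  for (p in seq_len(n)) {
    if (p == n || all(ch[seq_len(n - p)] == ch[seq.int(p + 1L, n)]))
      return(p)
  }
  n
}

# random repeat unit with minimal period u whose tandem repetition creates
# no detectable array of any other unit size
.random_unit <- function(u, thresholds = str_default_thresholds()) {
  repeat {
    ch <- .random_dna_chars(u)
    if (.min_period(ch) != u) next
    probe <- paste(rep(ch, ceiling(40 / u) + 2L), collapse = "")
    hits <- .scan_one(probe, 1L, 10L, thresholds)
    if (nrow(hits) > 0 && all(hits$unit_size == u)) return(ch)
  }
}

# Replace detector-visible arrays in unprotected positions with fresh
# random bases until none remain (rejection; protected spans are left).
.scrub_chars <- function(ch, protect = NULL, max_iter = 50L) {
  if (is.null(protect)) protect <- rep(FALSE, length(ch))
  for (iter in seq_len(max_iter)) {
    hits <- .scan_one(paste(ch, collapse = ""), 1L, 10L,
                      str_default_thresholds())
    dirty <- FALSE
    for (k in seq_len(nrow(hits))) {
      idx <- hits$start[k]:hits$end[k]
      idx <- idx[!protect[idx]]
      if (length(idx) > 0) {
        ch[idx] <- .random_dna_chars(length(idx))
        dirty <- TRUE
      }
    }
    if (!dirty) return(ch)
  }
  stop("scrubbing failed to converge")
}

# Write a tandem array into ch at [at, at+len-1] and break extension at the
# flanks. Returns the modified character vector.
.plant_array <- function(ch, at, len, unit) {
  u <- length(unit)
  tract <- rep(unit, length.out = len + 2L * u)
  ch[at:(at + len - 1L)] <- tract[(u + 1L):(u + len)]
  if (at > 1L && ch[at - 1L] == tract[u])
    ch[at - 1L] <- sample(setdiff(BASES, tract[u]), 1L)
  if (at + len <= length(ch) && ch[at + len] == tract[u + len + 1L])
    ch[at + len] <- sample(setdiff(BASES, tract[u + len + 1L]), 1L)
  ch
}

# Free-interval bookkeeping as a closure over parallel vectors: take a
# random slot of width len (plus 1 bp margins, length-weighted choice) and
# split the interval it came from.
.make_slotter <- function(free) {
  ctg <- free$contig; lo <- free$start; hi <- free$end
  take <- function(len) {
    w <- hi - lo + 1L - len - 1L
    ok <- which(w >= 1L)
    if (length(ok) == 0) return(NULL)
    pick <- ok[sample.int(length(ok), 1L, prob = w[ok])]
    a <- lo[pick] + 1L; b <- hi[pick] - len
    at <- if (b > a) a + sample.int(b - a + 1L, 1L) - 1L else a
    old_hi <- hi[pick]; id <- ctg[pick]
    hi[pick] <<- at - 2L
    if (old_hi >= at + len + 1L) {
      n <- length(ctg) + 1L
      ctg[n] <<- id; lo[n] <<- at + len + 1L; hi[n] <<- old_hi
    }
    list(contig = id, at = at)
  }
  list(take = take)
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))    # aa -> codons
})

.reverse_translate <- function(aa_chars) {
  unlist(lapply(aa_chars, function(a) {
    cods <- CODON_TABLE[[a]]
    strsplit(cods[sample.int(length(cods), 1L)], "")[[1]]
  }), use.names = FALSE)
}

# Synonymously recode codons overlapping detector-visible arrays until the
# coding sequence is array-free. aa_chars gives the translation.
.scrub_coding <- function(dna_chars, aa_chars, max_iter = 50L) {
  for (iter in seq_len(max_iter)) {
    hits <- .scan_one(paste(dna_chars, collapse = ""), 1L, 10L,
                      str_default_thresholds())
    if (nrow(hits) == 0) return(dna_chars)
    for (k in seq_len(nrow(hits))) {
      cod_idx <- unique((hits$start[k]:hits$end[k] - 1L) %/% 3L + 1L)
      for (ci in cod_idx) {
        repl <- .reverse_translate(aa_chars[ci])
        dna_chars[(3L * ci - 2L):(3L * ci)] <- repl
      }
    }
  }
  stop("coding-sequence scrubbing failed to converge")
}

# random consensus protein without immediately repeated residues and
# without single-codon residues (M, W) to keep recoding flexible
.random_consensus <- function(L) {
  pool <- setdiff(PROFILE_ALPHABET[1:20], c("M", "W"))
  out <- character(L)
  out[1] <- sample(pool, 1L)
  for (i in seq.int(2L, L))
    out[i] <- sample(setdiff(pool, out[i - 1L]), 1L)
  paste(out, collapse = "")
}

#' Simulate a genome with planted ground truth
#'
#' Writes a full dataset (FASTA assembly, GFF3 gene models, gene-to-GO
#' TSV, VCF variants, read-depth TSV, domain profiles, placed map) whose
#' every statistical feature is known by construction: planted STR arrays
#' hit the configured density spectrum exactly, background sequence is
#' kept array-free by rejection, gene STR status follows the configured
#' GO-level effect multipliers, size-3 indels sit inside genic
#' trinucleotide arrays in exactly the configured number of genes, and
#' domain-family copies (some pseudogenized, some collapsed at multiplied
#' read depth) live on dedicated contigs.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths) and `truth`
#'   (planted STR loci as `GRanges`, per-gene flags, term effects,
#'   variants with pass flags, domain copies, contig table, profiles,
#'   `assembly_bp`).
#' @export
simulate_genome <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- str_default_thresholds()
  min_len <- th$min_len

  ## ---- background contigs -------------------------------------------
  bg_ids <- sprintf("ctg%02d", seq_len(config$n_contigs))
  chars <- lapply(bg_ids, function(id)
    .scrub_chars(.random_dna_chars(config$contig_length)))
  names(chars) <- bg_ids
  protect <- lapply(chars, function(x) rep(FALSE, length(x)))

  ## ---- domain-contig geometry (lengths needed for total bp) ---------
  flank <- 300L
  dom_plan <- list()
  for (fam in names(config$domain_families)) {
    f <- config$domain_families[[fam]]
    n_res <- f$n_copies - sum(f$collapse)
    if (n_res < 0) stop("collapse multiplicities exceed n_copies for ", fam)
    n_pseudo <- round(f$pseudogene_fraction * n_res)
    pseudo_flags <- c(rep(TRUE, n_pseudo), rep(FALSE, n_res - n_pseudo))
    mult <- c(rep(1L, n_res), as.integer(f$collapse))
    pseudo_flags <- c(pseudo_flags, rep(FALSE, length(f$collapse)))
    ids <- sprintf("dom_%s_%02d", fam, seq_along(mult))
    dom_plan[[fam]] <- data.frame(
      seq_id = ids, family = fam, multiplicity = mult,
      pseudo = pseudo_flags,
      length = 2L * flank + 3L * f$consensus_length)
  }
  dom_plan_df <- if (length(dom_plan) > 0) do.call(rbind, dom_plan) else
    data.frame(seq_id = character(0), family = character(0),
               multiplicity = integer(0), pseudo = logical(0),
               length = integer(0))
  total_bp <- config$n_contigs * config$contig_length +
    sum(dom_plan_df$length)

  ## ---- gene placement -----------------------------------------------
  span_len <- config$exons_per_gene * config$exon_bp +
    (config$exons_per_gene - 1L) * config$intron_bp
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  g_contig <- character(config$n_genes)
  g_start <- integer(config$n_genes)
  ci <- 1L; cursor <- 1000L
  for (gi in seq_len(config$n_genes)) {
    if (cursor + span_len > config$contig_length - 1000L) {
      ci <- ci + 1L
      if (ci > config$n_contigs)
        stop("contigs too small for requested gene count")
      cursor <- 1000L
    }
    g_contig[gi] <- bg_ids[ci]
    g_start[gi] <- cursor
    cursor <- cursor + span_len + sample(800:1500, 1L)
  }
  g_end <- g_start + span_len - 1L
  exon_off <- (seq_len(config$exons_per_gene) - 1L) *
    (config$exon_bp + config$intron_bp)
  gene_gr <- GenomicRanges::GRanges(g_contig,
                                    IRanges::IRanges(g_start, g_end),
                                    strand = "+")
  names(gene_gr) <- gene_ids
  cds_list <- lapply(seq_len(config$n_genes), function(gi) {
    st <- g_start[gi] + exon_off
    GenomicRanges::GRanges(g_contig[gi],
                           IRanges::IRanges(st, st + config$exon_bp - 1L),
                           strand = "+")
  })
  cds_grl <- GenomicRanges::GRangesList(stats::setNames(cds_list, gene_ids))

  ## ---- GO vocabulary and per-gene STR probability -------------------
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  if (!all(names(config$enriched_terms) %in% c(terms, character(0))))
    stop("enriched_terms must name terms within n_go_terms")
  term_genes <- lapply(terms, function(t)
    sample(gene_ids,
           min(length(gene_ids),
               sample(config$genes_per_term[1]:config$genes_per_term[2],
                      1L))))
  names(term_genes) <- terms
  gene_terms <- split(rep(names(term_genes), lengths(term_genes)),
                      unlist(term_genes, use.names = FALSE))
  gene_terms <- stats::setNames(
    lapply(gene_ids, function(g) unname(gene_terms[[g]])), gene_ids)
  gene_mult <- vapply(gene_terms, function(tt) {
    e <- config$enriched_terms[names(config$enriched_terms) %in% tt]
    if (length(e) == 0) 1 else prod(e)
  }, numeric(1))
  p_gene <- pmin(0.95, config$base_str_p * gene_mult)
  has_str <- stats::runif(config$n_genes) < p_gene
  names(has_str) <- gene_ids

  ## ---- plant CDS trinucleotide arrays in STR-positive genes ---------
  unit_pool <- lapply(stats::setNames(1:10, 1:10), function(u)
    replicate(12, .random_unit(u, th), simplify = FALSE))
  planted <- list()
  cds_bp_u <- stats::setNames(numeric(10), 1:10)
  gene_str_locus <- stats::setNames(vector("list", config$n_genes), gene_ids)
  for (gi in which(has_str)) {
    ctg <- g_contig[gi]
    exon <- sample.int(config$exons_per_gene, 1L)
    ex_start <- g_start[gi] + exon_off[exon]
    len <- sample(18:30, 1L)
    at <- ex_start + 1L + sample.int(config$exon_bp - len - 2L, 1L)
    unit <- unit_pool[["3"]][[sample.int(12, 1L)]]
    chars[[ctg]] <- .plant_array(chars[[ctg]], at, len, unit)
    protect[[ctg]][max(1L, at - 1L):min(length(protect[[ctg]]), at + len)] <- TRUE
    rec <- data.frame(seq_id = ctg, start = at, end = at + len - 1L,
                      unit_size = 3L,
                      motif = canonical_motif(paste(unit, collapse = "")),
                      array_bp = len)
    planted[[length(planted) + 1L]] <- rec
    gene_str_locus[[gene_ids[gi]]] <- rec
    cds_bp_u["3"] <- cds_bp_u["3"] + len
  }

  ## ---- free intervals outside genes ---------------------------------
  margin <- 10L
  free <- do.call(rbind, lapply(bg_ids, function(id) {
    occ <- gene_gr[g_contig == id]
    occ_ir <- IRanges::IRanges(pmax(1L, BiocGenerics::start(occ) - margin),
                               pmin(config$contig_length,
                                    BiocGenerics::end(occ) + margin))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, config$contig_length),
                             IRanges::reduce(occ_ir))
    if (length(gaps) == 0) return(NULL)
    data.frame(contig = id, start = BiocGenerics::start(gaps),
               end = BiocGenerics::end(gaps))
  }))

  ## ---- intergenic arrays to hit the density spectrum ----------------
  ## placements are planned first (slot bookkeeping), then written per
  ## contig in one batch to avoid repeated whole-contig copies
  slotter <- .make_slotter(free)
  pl_ctg <- character(0); pl_at <- integer(0); pl_len <- integer(0)
  pl_u <- integer(0); pl_unit <- character(0)
  for (u in 1:10) {
    uu <- as.character(u)
    target <- round(config$str_spectrum[[uu]] * total_bp / 1e6)
    remaining <- target - cds_bp_u[[uu]]
    while (remaining >= min_len[[uu]]) {
      len <- min_len[[uu]] + stats::rgeom(1L, 0.15)
      len <- min(len, 200L, remaining)
      if (remaining - len < min_len[[uu]]) len <- remaining
      slot <- slotter$take(len)
      if (is.null(slot))
        stop("requested STR density infeasible for contig length (u=", u, ")")
      unit <- unit_pool[[uu]][[sample.int(12, 1L)]]
      n <- length(pl_ctg) + 1L
      pl_ctg[n] <- slot$contig; pl_at[n] <- slot$at; pl_len[n] <- len
      pl_u[n] <- u; pl_unit[n] <- paste(unit, collapse = "")
      remaining <- remaining - len
    }
  }
  for (id in unique(pl_ctg)) {
    ch <- chars[[id]]; pr <- protect[[id]]
    for (k in which(pl_ctg == id)) {
      at <- pl_at[k]; len <- pl_len[k]
      unit <- strsplit(pl_unit[k], "")[[1]]; u <- length(unit)
      tract <- rep(unit, length.out = len + 2L * u)
      ch[at:(at + len - 1L)] <- tract[(u + 1L):(u + len)]
      if (at > 1L && ch[at - 1L] == tract[u])
        ch[at - 1L] <- sample(setdiff(BASES, tract[u]), 1L)
      if (at + len <= length(ch) && ch[at + len] == tract[u + len + 1L])
        ch[at + len] <- sample(setdiff(BASES, tract[u + len + 1L]), 1L)
      pr[max(1L, at - 1L):min(length(pr), at + len)] <- TRUE
    }
    chars[[id]] <- ch; protect[[id]] <- pr
  }
  if (length(pl_ctg) > 0)
    planted[[length(planted) + 1L]] <- data.frame(
      seq_id = pl_ctg, start = pl_at, end = pl_at + pl_len - 1L,
      unit_size = pl_u, motif = canonical_motif(pl_unit),
      array_bp = pl_len)

  ## ---- domain families ----------------------------------------------
  profiles <- list()
  dom_truth <- list()
  for (fam in names(config$domain_families)) {
    f <- config$domain_families[[fam]]
    consensus <- .random_consensus(f$consensus_length)
    profiles[[fam]] <- domain_profile(fam, consensus)
    cons_chars <- strsplit(consensus, "")[[1]]
    plan <- dom_plan[[fam]]
    pool <- setdiff(PROFILE_ALPHABET[1:20], c("M", "W"))
    for (k in seq_len(nrow(plan))) {
      aa <- cons_chars
      n_mut <- max(1L, round(0.03 * length(aa)))
      mut_pos <- sample(seq.int(2L, length(aa) - 1L), n_mut)
      for (mp in mut_pos)
        aa[mp] <- sample(setdiff(pool, aa[c(mp - 1L, mp, mp + 1L)]), 1L)
      if (plan$pseudo[k])
        aa[length(aa) %/% 2L] <- "*"
      dna <- .reverse_translate(aa)
      dna <- .scrub_coding(dna, aa)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "-") rev(chartr("ACGT", "TGCA", dna)) else dna
      ctg_chars <- c(.scrub_chars(.random_dna_chars(flank)), ins,
                     .scrub_chars(.random_dna_chars(flank)))
      prot <- rep(FALSE, length(ctg_chars))
      prot[(flank + 1L):(flank + length(ins))] <- TRUE
      ctg_chars <- .scrub_chars(ctg_chars, prot)
      id <- plan$seq_id[k]
      chars[[id]] <- ctg_chars
      protect[[id]] <- prot
      dom_truth[[length(dom_truth) + 1L]] <- data.frame(
        seq_id = id, family = fam, start = flank + 1L,
        end = flank + length(ins), strand = strand,
        pseudo = plan$pseudo[k], multiplicity = plan$multiplicity[k])
    }
  }
  dom_truth <- if (length(dom_truth) > 0) do.call(rbind, dom_truth) else
    data.frame(seq_id = character(0), family = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               pseudo = logical(0), multiplicity = integer(0))

  ## ---- closed-loop verification of the planted STR landscape --------
  planted_df <- do.call(rbind, planted)
  key <- function(d) paste(d$seq_id, as.integer(d$start),
                           as.integer(d$end), as.integer(d$unit_size))
  for (iter in 1:10) {
    seqs <- Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                            collapse = ""))
    det <- find_strs(seqs)
    det_df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(det)),
                         start = BiocGenerics::start(det),
                         end = BiocGenerics::end(det),
                         unit_size = det$unit_size)
    extra <- det_df[!(key(det_df) %in% key(planted_df)), , drop = FALSE]
    if (nrow(extra) == 0) break
    for (k in seq_len(nrow(extra))) {
      idx <- extra$start[k]:extra$end[k]
      idx <- idx[!protect[[extra$seq_id[k]]][idx]]
      if (length(idx) == 0)
        stop("internal: accidental array entirely inside protected span")
      chars[[extra$seq_id[k]]][idx] <- .random_dna_chars(length(idx))
    }
    if (iter == 10) stop("internal: planted landscape failed to converge")
  }
  if (!setequal(key(det_df), key(planted_df)))
    stop("internal: detected loci do not match planted loci")

  ## ---- variants ------------------------------------------------------
  tri_gr <- GenomicRanges::GRanges(
    planted_df$seq_id[planted_df$unit_size == 3L],
    IRanges::IRanges(planted_df$start[planted_df$unit_size == 3L],
                     planted_df$end[planted_df$unit_size == 3L]))
  flagged <- names(which(has_str))
  if (length(flagged) < config$n_tri_indel_genes)
    stop("too few STR-carrying genes for n_tri_indel_genes")
  tri_genes <- sample(flagged, config$n_tri_indel_genes)
  draw_quality <- function(n, pass) {
    qual <- numeric(n); dp <- integer(n)
    qual[pass] <- stats::runif(sum(pass), 20.5, 60)
    dp[pass] <- 6L + stats::rpois(sum(pass), 20)
    bad_q <- pass == FALSE & stats::runif(n) < 0.5
    bad_d <- !pass & !bad_q
    qual[bad_q] <- stats::runif(sum(bad_q), 0, 20)
    dp[bad_q] <- 6L + stats::rpois(sum(bad_q), 20)
    qual[bad_d] <- stats::runif(sum(bad_d), 20.5, 60)
    dp[bad_d] <- sample(0:5, sum(bad_d), replace = TRUE)
    list(qual = qual, dp = dp)
  }
  base_at <- function(ctg, pos, len = 1L)
    paste(chars[[ctg]][pos:(pos + len - 1L)], collapse = "")
  variants <- list()
  # deliberate size-3 indels inside genic trinucleotide arrays
  for (g in tri_genes) {
    loc <- gene_str_locus[[g]]
    pos <- loc$start
    if (stats::runif(1) < 0.5) {   # insertion of one repeat unit
      ref <- base_at(loc$seq_id, pos)
      alt <- paste0(ref, base_at(loc$seq_id, pos + 1L, 3L))
    } else {                        # deletion of one repeat unit
      ref <- base_at(loc$seq_id, pos, 4L)
      alt <- base_at(loc$seq_id, pos)
    }
    variants[[length(variants) + 1L]] <- data.frame(
      seq_id = loc$seq_id, pos = pos, ref = ref, alt = alt,
      quality = stats::runif(1, 30, 60), depth = 20L + stats::rpois(1, 10),
      pass = TRUE, planted_tri = TRUE)
  }
  class_counts <- round(config$variant_rates * total_bp)
  class_counts["INDEL"] <- class_counts["INDEL"] - config$n_tri_indel_genes
  bg_len <- config$contig_length
  rand_pos <- function(n) {
    ctg <- sample(bg_ids, n, replace = TRUE)
    pos <- sample.int(bg_len - 20L, n, replace = TRUE) + 5L
    data.frame(ctg = ctg, pos = pos)
  }
  in_tri <- function(ctg, pos) {
    anch <- GenomicRanges::GRanges(ctg, IRanges::IRanges(pos + 1L, pos + 1L))
    IRanges::overlapsAny(anch, tri_gr)
  }
  other_base <- function(b) vapply(b, function(x)
    sample(setdiff(BASES, x), 1L), character(1), USE.NAMES = FALSE)
  for (cls in c("SNP", "MNP", "INDEL", "COMPLEX")) {
    n <- class_counts[[cls]]
    if (n <= 0) next
    pp <- rand_pos(n)
    ref <- character(n); alt <- character(n)
    if (cls == "SNP") {
      ref <- vapply(seq_len(n), function(i) base_at(pp$ctg[i], pp$pos[i]),
                    character(1))
      alt <- other_base(ref)
    } else if (cls == "MNP") {
      len <- sample(2:3, n, replace = TRUE)
      for (i in seq_len(n)) {
        ref[i] <- base_at(pp$ctg[i], pp$pos[i], len[i])
        alt[i] <- paste(other_base(strsplit(ref[i], "")[[1]]), collapse = "")
      }
    } else if (cls == "INDEL") {
      size <- sample(c(1:2, 4:6, 3L), n, replace = TRUE,
                     prob = c(rep(0.18, 5), 0.1))
      is_ins <- stats::runif(n) < 0.5
      redo <- which(size == 3L & in_tri(pp$ctg, pp$pos))
      while (length(redo) > 0) {
        np <- rand_pos(length(redo))
        pp$ctg[redo] <- np$ctg; pp$pos[redo] <- np$pos
        redo <- redo[in_tri(pp$ctg[redo], pp$pos[redo])]
      }
      for (i in seq_len(n)) {
        anchor <- base_at(pp$ctg[i], pp$pos[i])
        if (is_ins[i]) {
          ref[i] <- anchor
          alt[i] <- paste0(anchor,
                           paste(sample(BASES, size[i], replace = TRUE),
                                 collapse = ""))
        } else {
          ref[i] <- base_at(pp$ctg[i], pp$pos[i], size[i] + 1L)
          alt[i] <- anchor
        }
      }
    } else {  # COMPLEX
      for (i in seq_len(n)) {
        ref[i] <- base_at(pp$ctg[i], pp$pos[i], 3L)
        first <- other_base(substr(ref[i], 1L, 1L))
        alt[i] <- paste0(first, paste(sample(BASES, 4L, replace = TRUE),
                                      collapse = ""))
      }
    }
    pass <- stats::runif(n) < config$pass_fraction
    qd <- draw_quality(n, pass)
    variants[[length(variants) + 1L]] <- data.frame(
      seq_id = pp$ctg, pos = pp$pos, ref = ref, alt = alt,
      quality = qd$qual, depth = qd$dp, pass = pass, planted_tri = FALSE)
  }
  variants <- do.call(rbind, variants)
  cl <- classify_variant(variants$ref, variants$alt)
  variants$var_class <- cl$var_class
  variants$indel_size <- cl$indel_size

  ## ---- depth ---------------------------------------------------------
  contig_tab <- data.frame(
    seq_id = c(bg_ids, dom_plan_df$seq_id),
    length = c(rep(config$contig_length, config$n_contigs),
               dom_plan_df$length),
    multiplier = c(rep(1L, config$n_contigs), dom_plan_df$multiplicity),
    placed = c(rep(TRUE, config$n_contigs),
               rep(FALSE, nrow(dom_plan_df))))
  contig_tab$mean_depth <- vapply(seq_len(nrow(contig_tab)), function(i)
    stats::rpois(1L, contig_tab$length[i] * contig_tab$multiplier[i] *
                   config$base_depth) / contig_tab$length[i], numeric(1))

  ## ---- write files ---------------------------------------------------
  fa <- vapply(chars, paste, character(1), collapse = "")
  files <- c(
    assembly = file.path(out_dir, "assembly.fasta"),
    genes = file.path(out_dir, "genes.gff3"),
    go_map = file.path(out_dir, "go_map.tsv"),
    variants = file.path(out_dir, "variants.vcf"),
    depth = file.path(out_dir, "depth.tsv"),
    profiles = file.path(out_dir, "profiles.txt"),
    placed = file.path(out_dir, "placed.tsv"))
  write_assembly(fa, files[["assembly"]])
  models <- new_gene_models(gene_gr, cds_grl)
  write_gene_models(models, files[["genes"]])
  write_go_map(gene_terms[lengths(gene_terms) > 0], files[["go_map"]])
  write_vcf(variants[, c("seq_id", "pos", "ref", "alt", "quality", "depth")],
            files[["variants"]],
            contigs = stats::setNames(contig_tab$length, contig_tab$seq_id))
  utils::write.table(contig_tab[, c("seq_id", "mean_depth", "length")],
                     files[["depth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_profiles(profiles, files[["profiles"]])
  write_placed_map(stats::setNames(contig_tab$placed, contig_tab$seq_id),
                   files[["placed"]])

  str_truth <- GenomicRanges::GRanges(
    planted_df$seq_id, IRanges::IRanges(planted_df$start, planted_df$end))
  str_truth$unit_size <- planted_df$unit_size
  str_truth$motif <- planted_df$motif
  str_truth$array_bp <- planted_df$array_bp
  str_truth$copy_number <- planted_df$array_bp / planted_df$unit_size
  genes_truth <- data.frame(
    gene_id = gene_ids, seq_id = g_contig, start = g_start, end = g_end,
    has_str = unname(has_str),
    has_tri_indel = gene_ids %in% tri_genes,
    multiplier = unname(gene_mult), p_str = unname(p_gene))
  truth <- list(str_loci = BiocGenerics::sort(str_truth),
                genes = genes_truth,
                gene_terms = gene_terms,
                term_effects = config$enriched_terms,
                variants = variants,
                domains = dom_truth,
                contigs = contig_tab,
                profiles = profiles,
                assembly_bp = total_bp)
  ## truth tables as TSV for external use
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  utils::write.table(planted_df, file.path(tdir, "str_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genes_truth, file.path(tdir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(variants, file.path(tdir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dom_truth, file.path(tdir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(contig_tab, file.path(tdir, "contigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(files = files, truth = truth))
}

#' Simulate a dataset with all enrichment effects zeroed
#'
#' As [simulate_genome()] but every GO-term effect multiplier is 1, so the
#' per-gene STR probability is identical across terms: a type-I-error
#' harness for the enrichment stage.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory.
#' @return See [simulate_genome()].
#' @export
null_dataset <- function(config, out_dir) {
  config$enriched_terms[] <- 1
  simulate_genome(config, out_dir)
}

#' Fast count-level GO enrichment simulator
#'
#' Draws per-term with/without-STR gene counts directly (each term with
#' its own genes), for power and type-I-error studies of the
#' between-species tests without building sequence files. The effect is a
#' multiplier on the per-gene probability of carrying an STR - exactly the
#' quantity Fisher's test compares.
#'
#' @param species Character vector of species names.
#' @param n_terms Number of GO terms.
#' @param genes_per_term Genes annotated to each term.
#' @param base_p Baseline per-gene STR probability.
#' @param term_effects Named list: species -> named numeric of per-term
#'   probability multipliers (terms not listed get 1).
#' @return Named list of `data.frame`s (`go_id`, `n_with`, `n_without`),
#'   one per species, usable with [pairwise_species_tests()].
#' @export
simulate_go_counts <- function(species = c("A", "B"), n_terms = 510L,
                               genes_per_term = 200L, base_p = 0.15,
                               term_effects = list()) {
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  out <- lapply(species, function(sp) {
    p <- rep(base_p, n_terms)
    eff <- term_effects[[sp]]
    if (!is.null(eff)) {
      idx <- match(names(eff), terms)
      if (any(is.na(idx))) stop("unknown term in term_effects")
      p[idx] <- pmin(1, p[idx] * eff)
    }
    n_with <- stats::rbinom(n_terms, genes_per_term, p)
    data.frame(go_id = terms, n_with = n_with,
               n_without = genes_per_term - n_with)
  })
  stats::setNames(out, species)
}
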
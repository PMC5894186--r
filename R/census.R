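#' Six-frame domain census of an assembly
#'
#' Translates every sequence in all six frames, scans each frame with each
#' profile, back-projects hits to genomic coordinates, and deduplicates
#' hits from different frames whose genomic intervals overlap reciprocally
#' by at least 50% (best score kept). Reports, per profile, the coverage
#' bins used for copy-number proxies: all hits, >50% and >75% of the
#' domain length, >75% with internal stop codons (pseudogene candidates),
#' and the placed/unplaced split.
#'
#' @param assembly `DNAStringSet` (named).
#' @param profiles List of `domain_profile` objects.
#' @param placed_map Optional named logical (seq_id -> placed). Sequences
#'   missing from the map are treated as unplaced with a warning.
#' @return List with `hits` (deduplicated `data.frame`: `profile`,
#'   `seq_id`, `frame`, `g_start`, `g_end`, `coverage`, `score`,
#'   `has_internal_stop`, `placed`), `raw_hits` (before deduplication) and
#'   `report` (one row per profile: `n_all`, `n_gt50`, `n_gt75`,
#'   `n_gt75_with_stops`, `n_placed`, `n_unplaced`, `n_raw`).
#' @export
census <- function(assembly, profiles, placed_map = NULL) {
  if (is.null(names(assembly)) && length(assembly) > 0)
    stop("assembly sequences must be named")
  if (inherits(profiles, "domain_profile")) profiles <- list(profiles)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  rows <- list()
  for (si in seq_along(assembly)) {
    seq_id <- names(assembly)[si]
    n <- length(assembly[[si]])
    if (n < 3) next
    frames <- six_frame_translate(assembly[[si]])
    for (fr_name in names(frames)) {
      fr <- as.integer(fr_name)
      prot <- frames[[fr_name]]
      if (!nzchar(prot)) next
      for (p in profiles) {
        h <- profile_scan(prot, p)
        if (nrow(h) == 0) next
        g <- t(vapply(seq_len(nrow(h)), function(i)
          .backproject(h$start[i], h$end[i], fr, n), integer(2)))
        rows[[length(rows) + 1L]] <- data.frame(
          profile = p$name, seq_id = seq_id, frame = fr,
          g_start = g[, 1], g_end = g[, 2],
          coverage = h$coverage, score = h$score,
          has_internal_stop = h$has_internal_stop)
      }
    }
  }
  raw <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(profile = character(0), seq_id = character(0),
               frame = integer(0), g_start = integer(0),
               g_end = integer(0), coverage = numeric(0),
               score = numeric(0), has_internal_stop = logical(0))
  dedup <- .dedup_hits(raw)
  known <- if (is.null(placed_map)) character(0) else names(placed_map)
  resolve_placed <- function(ids) {
    placed <- rep(FALSE, length(ids))
    if (!is.null(placed_map)) {
      miss <- !(ids %in% known)
      if (any(miss))
        warning(sum(miss), " hit(s) on sequences absent from placed map, ",
                "treated unplaced")
      placed[!miss] <- placed_map[ids[!miss]]
    }
    placed
  }
  if (nrow(dedup) > 0) dedup$placed <- resolve_placed(dedup$seq_id)
  else dedup$placed <- logical(0)
  report <- do.call(rbind, lapply(names(profiles), function(pn) {
    d <- dedup[dedup$profile == pn, , drop = FALSE]
    data.frame(profile = pn,
               n_all = nrow(d),
               n_gt50 = sum(d$coverage > 0.5),
               n_gt75 = sum(d$coverage > 0.75),
               n_gt75_with_stops = sum(d$coverage > 0.75 &
                                         d$has_internal_stop),
               n_placed = sum(d$placed),
               n_unplaced = sum(!d$placed),
               n_raw = sum(raw$profile == pn))
  }))
  list(hits = dedup, raw_hits = raw, report = report)
}

# Greedy cross-frame deduplication: hits of the same profile on the same
# sequence are merged when their genomic intervals overlap >= 50%
# reciprocally; the best-scoring hit wins.
.dedup_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$profile, hits$seq_id))) {
    ord <- grp[order(hits$score[grp], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      drop <- FALSE
      for (k in kept) {
        ov <- min(hits$g_end[i], hits$g_end[k]) -
          max(hits$g_start[i], hits$g_start[k]) + 1L
        if (ov > 0) {
          wi <- hits$g_end[i] - hits$g_start[i] + 1L
          wk <- hits$g_end[k] - hits$g_start[k] + 1L
          if (ov >= 0.5 * wi && ov >= 0.5 * wk) { drop <- TRUE; break }
        }
      }
      if (!drop) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$profile, out$seq_id, out$g_start), , drop = FALSE]
}

#' Classify copy completeness from CDS coverage
#'
#' Full-length versus partial copy classification with inclusive bounds:
#' coverage at or above `full_threshold` is `full_length`, at or above
#' `partial_threshold` is `partial` (incomplete copies covering >= 60% of
#' the gene by default), anything less is `below`.
#'
#' @param coverage Numeric vector in `[0, 1]`.
#' @param full_threshold Default 1.0.
#' @param partial_threshold Default 0.60.
#' @return Factor with levels `full_length`, `partial`, `below`.
#' @export
classify_copy_completeness <- function(coverage, full_threshold = 1.0,
                                       partial_threshold = 0.60) {
  if (any(coverage < 0 | coverage > 1)) stop("coverage must be in [0, 1]")
  out <- ifelse(coverage >= full_threshold, "full_length",
                ifelse(coverage >= partial_threshold, "partial", "below"))
  factor(out, levels = c("full_length", "partial", "below"))
}

#' Classify MHC-class-I-style regions by alpha-domain co-occurrence
#'
#' Windows of `± window_bp` anchored on domain hits are resolved greedily
#' left to right per sequence: the leftmost unused hit anchors a window,
#' every unused hit intersecting the window joins the region, and the
#' region label is the sorted set of distinct domains present (e.g.
#' `a1+a2+a3` for a complete gene proxy, `a3` for an isolated fragment).
#'
#' @param hits `data.frame` with columns `seq_id`, `domain` (e.g. `"a1"`,
#'   `"a2"`, `"a3"`), `g_start`, `g_end`.
#' @param window_bp Half-window in bp (default 10000).
#' @return `data.frame` of regions: `seq_id`, `start`, `end`, `label`,
#'   `n_hits`.
#' @export
classify_mhc_region <- function(hits, window_bp = 10000) {
  if (nrow(hits) == 0)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      n_hits = integer(0)))
  regions <- list()
  for (sid in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == sid, , drop = FALSE]
    h <- h[order(h$g_start), , drop = FALSE]
    used <- rep(FALSE, nrow(h))
    while (any(!used)) {
      anchor <- which(!used)[1]
      w_lo <- h$g_start[anchor] - window_bp
      w_hi <- h$g_end[anchor] + window_bp
      member <- !used & h$g_start <= w_hi & h$g_end >= w_lo
      used[member] <- TRUE
      doms <- sort(unique(h$domain[member]))
      regions[[length(regions) + 1L]] <- data.frame(
        seq_id = sid,
        start = min(h$g_start[member]), end = max(h$g_end[member]),
        label = paste(doms, collapse = "+"),
        n_hits = sum(member))
    }
  }
  do.call(rbind, regions)
}
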
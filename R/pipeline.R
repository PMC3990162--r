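# End-to-end driver: segmentation and calling for every sample, the CNV /
# non-progressive filtering cascade, recurrent-region construction and
# sequential-recurrence classification. Plus helpers for scoring calls and
# regions against a simulated truth set.

#' Run the full progression analysis on a cohort
#'
#' Segments and calls every profile, filters population CNVs from both
#' groups, subtracts non-progressive alterations from the progressive call
#' set, builds recurrent regions from the surviving progressive calls and
#' classifies them by sequential recurrence.
#'
#' @param profiles named list of [probe_profile()].
#' @param metas a `sample_meta` data frame covering all profiles.
#' @param catalog a [cnv_catalog()]; `NULL` skips the CNV filter.
#' @param params a [segmentation_params()].
#' @param min_reciprocal_overlap overlap threshold used throughout.
#' @param max_population_frequency CNV rarity cap, default 0.01.
#' @return list with `calls` (all non-neutral calls), `segments`,
#'   `filter_report` (`n_input`, `n_after_cnv_filter`,
#'   `n_after_subtraction` for the progressive arm), `progressive_calls`
#'   (post-cascade), `regions`, `recurrence`, `freq_table`.
#' @export
progression_analysis <- function(profiles, metas, catalog = NULL,
                                 params = segmentation_params(),
                                 min_reciprocal_overlap = 0.5,
                                 max_population_frequency = 0.01) {
  stopifnot(all(names(profiles) %in% metas$sample_id))
  segs <- lapply(profiles, segment_profile, params = params)
  calls <- do.call(rbind, lapply(segs, call_segments, params = params,
                                 drop_neutral = TRUE))
  rownames(calls) <- NULL
  grp <- metas$group[match(calls$sample_id, metas$sample_id)]
  prog <- calls[grp %in% c("PL", "OSCC"), , drop = FALSE]
  nonprog <- calls[grp == "NPL", , drop = FALSE]
  n_input <- nrow(prog)
  if (!is.null(catalog)) {
    fp <- filter_population_cnvs(prog, catalog, min_reciprocal_overlap,
                                 max_population_frequency)
    prog <- fp$kept
    fn <- filter_population_cnvs(nonprog, catalog, min_reciprocal_overlap,
                                 max_population_frequency)
    nonprog <- fn$kept
  }
  n_cnv <- nrow(prog)
  sub <- subtract_group_cnas(prog, nonprog, min_reciprocal_overlap)
  prog <- sub$kept
  regions <- if (nrow(prog) > 0L &&
                 length(unique(prog$sample_id)) >= 2L) {
    build_recurrent_regions(prog, metas, min_reciprocal_overlap)
  } else NULL
  rec <- if (!is.null(regions)) sequential_recurrence(regions, metas) else
    NULL
  ft <- if (!is.null(regions)) frequency_table(regions, metas) else NULL
  list(calls = calls,
       segments = do.call(rbind, c(segs, list(make.row.names = FALSE))),
       filter_report = data.frame(n_input = n_input,
                                  n_after_cnv_filter = n_cnv,
                                  n_after_subtraction = nrow(prog)),
       progressive_calls = prog, regions = regions, recurrence = rec,
       freq_table = ft)
}

#' Score calls against an implanted truth set
#'
#' A call matches a truth event iff same sample, same direction, and
#' reciprocal overlap at least `min_ro`. Recall is the fraction of truth
#' events matched by some call; precision the fraction of non-neutral calls
#' matching some truth event.
#'
#' @param calls non-neutral calls data frame.
#' @param truth truth data frame (`sample_id`, `chrom`, `start`, `end`,
#'   `direction`).
#' @param min_ro matching threshold, default 0.5.
#' @return list with `recall`, `precision`, `n_truth`, `n_calls`.
#' @export
call_performance <- function(calls, truth, min_ro = 0.5) {
  calls <- calls[calls$direction != "neutral", , drop = FALSE]
  matched_truth <- logical(nrow(truth))
  matched_call <- logical(nrow(calls))
  for (s in unique(truth$sample_id)) {
    ti <- which(truth$sample_id == s)
    ci <- which(calls$sample_id == s)
    if (length(ci) == 0L) next
    hits <- .ro_hits(truth[ti, , drop = FALSE], calls[ci, , drop = FALSE],
                     min_ro)
    matched_truth[ti[unique(hits$query_idx)]] <- TRUE
    matched_call[ci[unique(hits$subject_idx)]] <- TRUE
  }
  list(recall = mean(matched_truth), precision = mean(matched_call),
       n_truth = nrow(truth), n_calls = nrow(calls))
}

#' Jaccard agreement between a region set and a truth interval set
#'
#' Regions and truth intervals are matched greedily one-to-one at reciprocal
#' overlap `>= min_ro` with direction agreement; the Jaccard index is
#' matches / (n_regions + n_truth - matches).
#'
#' @param regions data frame with `chrom`, `start`, `end`, `direction`.
#' @param truth data frame with the same columns (distinct intervals).
#' @param min_ro matching threshold, default 0.5.
#' @return Jaccard index in \[0, 1\].
#' @export
region_jaccard <- function(regions, truth, min_ro = 0.5) {
  if (nrow(regions) == 0L && nrow(truth) == 0L) return(1)
  hits <- .ro_hits(regions, truth, min_ro)
  hits <- hits[order(-hits$ro), , drop = FALSE]
  used_q <- logical(nrow(regions)); used_s <- logical(nrow(truth))
  m <- 0L
  for (i in seq_len(nrow(hits))) {
    q <- hits$query_idx[i]; s <- hits$subject_idx[i]
    if (!used_q[q] && !used_s[s]) {
      used_q[q] <- used_s[s] <- TRUE
      m <- m + 1L
    }
  }
  m / (nrow(regions) + nrow(truth) - m)
}
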
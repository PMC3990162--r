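# Change-point segmentation of probe-level log2-ratio profiles.
#
# Algorithm: per chromosome, recursive top-down binary splitting. At each
# step the breakpoint maximizing the two-sample Welch t statistic between
# the left and right flanks is chosen (leftmost on ties); the split is
# accepted iff its Satterthwaite p-value is below the stringency threshold
# and both children keep at least the minimum marker count. A bottom-up
# merge pass then collapses adjacent segments whose separation fails either
# the p-value criterion or the signal-to-noise criterion
# |delta mean| / pooled SD >= snr_threshold.

#' Segmentation parameters
#'
#' Defaults follow the published stringency: 10 consecutive markers,
#' split p-value cut-off 0.001, signal-to-noise cut-off 0.3, and linear-ratio
#' call thresholds 1.15 (gain) / 0.85 (loss) around a diploid baseline of 1.
#'
#' @param min_markers minimum probes per segment (count, default 10).
#' @param split_p_threshold two-sided p-value required to accept a split.
#' @param snr_threshold minimum |delta mean| / pooled SD between adjacent
#'   segments (dimensionless, log2 scale).
#' @param gain_ratio linear ratio above which a segment is a gain.
#' @param loss_ratio linear ratio below which a segment is a loss.
#' @param flank_window maximum probes per flank used by the split
#'   statistic (default 5x `min_markers`). Localizing the two-sample test
#'   keeps short events detectable: with unbounded flanks the statistic at
#'   a short event's edge is diluted by the long flank's length.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(min_markers = 10L, split_p_threshold = 0.001,
                                snr_threshold = 0.3, gain_ratio = 1.15,
                                loss_ratio = 0.85,
                                flank_window = 5L * min_markers) {
  stopifnot(min_markers >= 2L, split_p_threshold > 0, split_p_threshold < 1,
            snr_threshold >= 0, loss_ratio > 0, loss_ratio < 1,
            gain_ratio > 1, flank_window >= min_markers)
  structure(list(min_markers = as.integer(min_markers),
                 split_p_threshold = split_p_threshold,
                 snr_threshold = snr_threshold,
                 gain_ratio = gain_ratio, loss_ratio = loss_ratio,
                 flank_window = as.integer(flank_window)),
            class = "segmentation_params")
}

# Welch two-sample t statistic and p-value from summary statistics.
# Both-variances-zero is the noiseless degenerate case: p = 0 if the means
# differ (split retained), p = 1 otherwise.
.welch <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) {
    return(list(t = if (m1 != m2) Inf else 0,
                p = if (m1 != m2) 0 else 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  if (!is.finite(df) || df <= 0) df <- n1 + n2 - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Probe-count-weighted pooled SD of two segments; the SNR denominator.
.pooled_sd <- function(v1, n1, v2, n2) sqrt((n1 * v1 + n2 * v2) / (n1 + n2))

.seg_var <- function(x) if (length(x) < 2L) 0 else stats::var(x)

# Recursive binary splitting of x[lo..hi]; returns interior breakpoints
# (index of the last probe of the left child). Uses prefix sums for O(n)
# candidate evaluation per split.
.split_recursive <- function(x, cs, cs2, lo, hi, params) {
  n <- hi - lo + 1L
  flank <- max(params$min_markers, 3L)   # Welch needs >= 3 probes per flank
  if (n < 2L * flank) return(integer())
  ks <- (lo + flank - 1L):(hi - flank)
  # flanks truncated to the local window so short events are not diluted
  # by long constant stretches
  W <- params$flank_window
  ll <- pmax(lo, ks - W + 1L)
  rr <- pmin(hi, ks + W)
  nl <- ks - ll + 1L
  nr <- rr - ks
  sl <- cs[ks + 1L] - cs[ll]
  sr <- cs[rr + 1L] - cs[ks + 1L]
  s2l <- cs2[ks + 1L] - cs2[ll]
  s2r <- cs2[rr + 1L] - cs2[ks + 1L]
  ml <- sl / nl; mr <- sr / nr
  vl <- pmax(0, (s2l - nl * ml^2) / (nl - 1L))
  vr <- pmax(0, (s2r - nr * mr^2) / (nr - 1L))
  se2 <- vl / nl + vr / nr
  tstat <- ifelse(se2 > 0, abs(ml - mr) / sqrt(se2),
                  ifelse(ml != mr, Inf, 0))
  best <- which.max(tstat)               # leftmost maximum (which.max ties)
  k <- ks[best]
  w <- .welch(ml[best], vl[best], nl[best], mr[best], vr[best], nr[best])
  # Bonferroni over the candidate breakpoints: the chosen breakpoint
  # maximizes the t statistic over length(ks) positions, so its pointwise
  # p-value is anti-conservative and would admit spurious splits
  p_adj <- min(1, w$p * length(ks))
  if (p_adj >= params$split_p_threshold) return(integer())
  c(.split_recursive(x, cs, cs2, lo, k, params), k,
    .split_recursive(x, cs, cs2, k + 1L, hi, params))
}

# Merge pass: collapse the leftmost adjacent pair failing either the p-value
# or the SNR criterion, until every adjacent pair passes both.
.merge_pass <- function(x, breaks, lo, hi, params) {
  repeat {
    if (length(breaks) == 0L) return(breaks)
    bounds <- c(lo - 1L, breaks, hi)
    failed <- NA_integer_
    for (i in seq_along(breaks)) {
      li <- (bounds[i] + 1L):bounds[i + 1L]
      ri <- (bounds[i + 1L] + 1L):bounds[i + 2L]
      xl <- x[li]; xr <- x[ri]
      vl <- .seg_var(xl); vr <- .seg_var(xr)
      ml <- mean(xl); mr <- mean(xr)
      w <- .welch(ml, vl, length(xl), mr, vr, length(xr))
      psd <- .pooled_sd(vl, length(xl), vr, length(xr))
      snr <- if (psd == 0) {
        if (ml != mr) Inf else 0
      } else abs(ml - mr) / psd
      if (!(w$p < params$split_p_threshold && snr >= params$snr_threshold)) {
        failed <- i
        break
      }
    }
    if (is.na(failed)) return(breaks)
    breaks <- breaks[-failed]
  }
}

#' Segment a probe profile into regions of constant copy number
#'
#' Each chromosome's probes are partitioned into contiguous segments with at
#' least `min_markers` probes; every adjacent pair of returned segments
#' differs at Welch-test `p < split_p_threshold` with signal-to-noise ratio
#' at least `snr_threshold`. Chromosomes with fewer than `min_markers`
#' probes yield a single unsplit segment.
#'
#' @param profile a [probe_profile()].
#' @param params a [segmentation_params()].
#' @return data frame of segments: `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open, from first probe position to last probe position
#'   + 1), `mean_log2`, `sd_log2`, `n_markers`, plus probe index columns
#'   `first_probe`/`last_probe` within the chromosome.
#' @export
segment_profile <- function(profile, params = segmentation_params()) {
  if (nrow(profile) == 0L) stop("empty profile")
  chroms <- unique(profile$chrom)
  res <- lapply(chroms, function(ch) {
    sel <- profile$chrom == ch
    x <- profile$log2_ratio[sel]
    pos <- profile$pos[sel]
    n <- length(x)
    breaks <- integer()
    if (n >= 2L * params$min_markers) {
      cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
      breaks <- .split_recursive(x, cs, cs2, 1L, n, params)
      breaks <- .merge_pass(x, breaks, 1L, n, params)
    }
    bounds <- c(0L, breaks, n)
    k <- length(bounds) - 1L
    first <- bounds[-length(bounds)] + 1L
    last <- bounds[-1]
    data.frame(
      sample_id = sample_id(profile) %||% NA_character_,
      chrom = ch,
      start = pos[first],
      end = pos[last] + 1,
      mean_log2 = vapply(seq_len(k),
                         function(i) mean(x[first[i]:last[i]]), numeric(1)),
      sd_log2 = vapply(seq_len(k),
                       function(i) sqrt(.seg_var(x[first[i]:last[i]])),
                       numeric(1)),
      n_markers = last - first + 1L,
      first_probe = first, last_probe = last,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call gains and losses from segments
#'
#' A segment is a gain iff its linear ratio `2^mean_log2` exceeds
#' `gain_ratio`, a loss iff it is below `loss_ratio`, neutral otherwise.
#' Neutral segments are retained with `direction = "neutral"`.
#'
#' @param segments output of [segment_profile()].
#' @param params a [segmentation_params()].
#' @param drop_neutral drop neutral segments from the result? Default `FALSE`.
#' @return the segments data frame with added `direction` and `linear_ratio`
#'   columns.
#' @export
call_segments <- function(segments, params = segmentation_params(),
                          drop_neutral = FALSE) {
  lr <- 2^segments$mean_log2
  dir <- ifelse(lr > params$gain_ratio, "gain",
                ifelse(lr < params$loss_ratio, "loss", "neutral"))
  segments$direction <- dir
  segments$linear_ratio <- lr
  if (drop_neutral) segments <- segments[segments$direction != "neutral", ,
                                         drop = FALSE]
  rownames(segments) <- NULL
  segments
}

#' Concordance between two profiles on the same probe grid
#'
#' Quantifies the fidelity of a re-measured profile (e.g. whole-genome
#' amplified vs unamplified material) as the squared Pearson correlation of
#' paired log2 ratios and the mean absolute deviation of the log2 ratios
#' across all probes.
#'
#' @param a,b [probe_profile()] objects on an identical (chromosome,
#'   position) grid.
#' @return list with `r_squared`, `mean_abs_dev_log2`, `n_probes`.
#'   `r_squared` is `NA` with a warning when either profile has zero
#'   variance.
#' @export
profile_concordance <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom) || !all(a$pos == b$pos)) {
    stop("profiles must share an identical probe grid")
  }
  if (nrow(a) < 2L) stop("need at least 2 shared probes")
  mad_log2 <- mean(abs(a$log2_ratio - b$log2_ratio))
  if (stats::sd(a$log2_ratio) == 0 || stats::sd(b$log2_ratio) == 0) {
    warning("zero variance in a profile; r_squared undefined")
    r2 <- NA_real_
  } else {
    r2 <- stats::cor(a$log2_ratio, b$log2_ratio)^2
  }
  list(r_squared = r2, mean_abs_dev_log2 = mad_log2, n_probes = nrow(a))
}
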
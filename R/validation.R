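# Validation-arm statistics: delta-delta-Ct relative quantification from
# RQ-PCR Ct tables, the Kruskal-Wallis group comparison, and the two-sided
# Fisher's exact test used for the tobacco association.

#' Construct a table of Ct records
#'
#' @param sample_id,gene,ct_target,ct_reference parallel vectors; Ct values
#'   in cycles, open interval (0, 45).
#' @param replicate replicate index, default 1.
#' @return a validated `ct_records` data frame.
#' @export
ct_records <- function(sample_id, gene, ct_target, ct_reference,
                       replicate = 1L) {
  df <- data.frame(sample_id = as.character(sample_id),
                   gene = as.character(gene),
                   ct_target = as.numeric(ct_target),
                   ct_reference = as.numeric(ct_reference),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  ok <- df$ct_target > 0 & df$ct_target < 45 &
    df$ct_reference > 0 & df$ct_reference < 45
  if (!all(ok)) stop("Ct values must lie in (0, 45)")
  class(df) <- c("ct_records", "data.frame")
  df
}

# Replicate-averaged delta-Ct (target - reference) for one sample x gene.
.delta_ct <- function(records) {
  mean(records$ct_target) - mean(records$ct_reference)
}

#' Relative DNA quantity by the delta-delta-Ct method
#'
#' Replicates are averaged on the Ct scale; `dCt = Ct_target -
#' Ct_reference` per sample, `ddCt = dCt_sample - dCt_calibrator`, and the
#' relative quantity is `2^-ddCt` (amplification efficiency fixed at 2 per
#' cycle). The calibrator must carry the same gene.
#'
#' @param record `ct_records` rows for one sample x gene (>= 1 replicate).
#' @param calibrator `ct_records` rows for the calibrator (normal-control)
#'   sample, same gene.
#' @return fold change (dimensionless).
#' @export
delta_delta_ct <- function(record, calibrator) {
  if (length(unique(record$gene)) != 1L ||
      length(unique(calibrator$gene)) != 1L ||
      record$gene[1] != calibrator$gene[1]) {
    stop("record and calibrator must share a single gene")
  }
  2^(-(.delta_ct(record) - .delta_ct(calibrator)))
}

#' Per-sample fold changes for every gene in a Ct table
#'
#' @param records a [ct_records()] table.
#' @param calibrator_sample sample id of the calibrator present in
#'   `records` for every gene.
#' @return data frame `sample_id`, `gene`, `fold`.
#' @export
ddct_table <- function(records, calibrator_sample) {
  out <- list()
  for (g in unique(records$gene)) {
    rg <- records[records$gene == g, , drop = FALSE]
    cal <- rg[rg$sample_id == calibrator_sample, , drop = FALSE]
    if (nrow(cal) == 0L) stop("calibrator sample has no Ct for gene ", g)
    for (s in unique(rg$sample_id)) {
      rec <- rg[rg$sample_id == s, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, gene = g, fold = delta_delta_ct(rec, cal),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (backed by [stats::kruskal.test]). All observations identical
#' gives H = 0 and p = 1.
#'
#' @param groups list of >= 2 numeric vectors of fold values, each
#'   non-empty, total n >= 3.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  if (sum(lengths(groups)) < 3L) stop("need total n >= 3")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability convention: the p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (relative tolerance 1e-12).
#' Any zero margin gives p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups, columns =
#'   exposure yes/no), or a length-4 vector `(a, b, c, d)` filled by row.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(17, 2, 5, 8), 2, 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.vector(table) && length(table) == 4L) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0),
            sum(table) > 0)
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
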
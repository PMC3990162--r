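# Unsupervised hierarchical clustering of per-sample copy-number profiles
# (Euclidean distance, average linkage, agglomerative) and a quantitative
# score for the separation of progressive from non-progressive samples.

#' Build a sample-by-feature matrix from profiles or calls
#'
#' `binned_log2` mode averages probe log2 ratios in fixed genomic bins
#' (empty bins carry 0); all profiles must share the probe grid.
#' `call_indicator` mode marks each bin +1 when overlapped by a gain call
#' only, -1 by a loss call only, 0 otherwise.
#'
#' @param x named list of [probe_profile()] (mode `binned_log2`) or a calls
#'   data frame (mode `call_indicator`).
#' @param mode `"binned_log2"` (default) or `"call_indicator"`.
#' @param bin_size bin width in bp, default 1e5.
#' @param genome optional data frame `chrom`/`length` defining bins for
#'   `call_indicator` mode; inferred from the calls when `NULL`.
#' @return numeric matrix, rows = samples, columns = bins
#'   (`chrom:binindex`).
#' @export
build_feature_matrix <- function(x, mode = c("binned_log2", "call_indicator"),
                                 bin_size = 1e5, genome = NULL) {
  mode <- match.arg(mode)
  if (mode == "binned_log2") {
    stopifnot(is.list(x), length(x) >= 1L)
    ref <- x[[1]]
    for (p in x) {
      if (nrow(p) != nrow(ref) || !all(p$chrom == ref$chrom) ||
          !all(p$pos == ref$pos)) {
        stop("all profiles must share the probe grid in binned_log2 mode")
      }
    }
    bin <- paste0(ref$chrom, ":", floor(ref$pos / bin_size))
    bin <- factor(bin, levels = unique(bin))
    m <- t(vapply(x, function(p) {
      as.numeric(tapply(p$log2_ratio, bin, mean))
    }, numeric(nlevels(bin))))
    colnames(m) <- levels(bin)
    rownames(m) <- if (!is.null(names(x))) names(x) else
      vapply(x, sample_id, character(1))
    m
  } else {
    calls <- x
    stopifnot(is.data.frame(calls))
    if (is.null(genome)) {
      genome <- do.call(rbind, lapply(split(calls, calls$chrom), function(d) {
        data.frame(chrom = d$chrom[1], length = max(d$end))
      }))
    }
    bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
      nb <- ceiling(genome$length[i] / bin_size)
      data.frame(chrom = genome$chrom[i], idx = seq_len(nb) - 1L,
                 start = (seq_len(nb) - 1L) * bin_size,
                 end = seq_len(nb) * bin_size, stringsAsFactors = FALSE)
    }))
    samples <- sort(unique(calls$sample_id))
    m <- matrix(0, length(samples), nrow(bins),
                dimnames = list(samples, paste0(bins$chrom, ":", bins$idx)))
    for (s in samples) {
      cs <- calls[calls$sample_id == s & calls$direction != "neutral", ,
                  drop = FALSE]
      if (nrow(cs) == 0L) next
      for (d in c("gain", "loss")) {
        cd <- cs[cs$direction == d, , drop = FALSE]
        if (nrow(cd) == 0L) next
        hit <- vapply(seq_len(nrow(bins)), function(b) {
          any(cd$chrom == bins$chrom[b] & cd$start < bins$end[b] &
                cd$end > bins$start[b])
        }, logical(1))
        m[s, hit] <- m[s, hit] + if (d == "gain") 1 else -1
      }
    }
    m[m > 1] <- 1; m[m < -1] <- -1
    m
  }
}

#' Hierarchically cluster samples
#'
#' Agglomerative clustering with average linkage (UPGMA) on Euclidean
#' distances between the rows of the feature matrix, optionally standardized
#' per feature first.
#'
#' @param matrix a sample-by-feature numeric matrix (>= 2 rows).
#' @param standardize scale features to unit variance first? Default
#'   `FALSE` (the analysis clusters raw log2 ratios).
#' @return an [stats::hclust] object.
#' @export
cluster_samples <- function(matrix, standardize = FALSE) {
  if (nrow(matrix) < 2L) stop("need >= 2 samples to cluster")
  if (standardize) {
    sds <- apply(matrix, 2, stats::sd)
    sds[sds == 0] <- 1
    matrix <- sweep(matrix, 2, sds, "/")
  }
  stats::hclust(stats::dist(matrix, method = "euclidean"),
                method = "average")
}

#' Adjusted Rand index between two partitions
#' @param a,b integer/character vectors of cluster labels, same length.
#' @return chance-corrected agreement in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / denom
}

#' Separation of disease groups in the dendrogram
#'
#' Cuts the tree into `k` clusters and cross-tabulates cluster membership
#' against the two disease classes (progressive lesions with their
#' carcinomas, `PL`/`OSCC`, versus `NPL`/`NORMAL` controls), reporting the
#' adjusted Rand index as the chance-corrected agreement score.
#'
#' @param hc an [stats::hclust] from [cluster_samples()]; leaf labels must
#'   be sample ids present in `metas`.
#' @param metas a `sample_meta` data frame.
#' @param k number of clusters to cut, default 2.
#' @return list with `contingency` (clusters x classes table) and
#'   `agreement` (adjusted Rand index).
#' @export
cluster_separation <- function(hc, metas, k = 2L) {
  cl <- stats::cutree(hc, k = k)
  grp <- metas$group[match(names(cl), metas$sample_id)]
  if (any(is.na(grp))) stop("dendrogram leaves missing from sample sheet")
  lab <- ifelse(grp %in% c("PL", "OSCC"), "progressive", "control")
  list(contingency = table(cluster = cl, class = lab),
       agreement = adjusted_rand_index(cl, lab))
}

#' Write a dendrogram in Newick format
#' @param hc an [stats::hclust] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  nleaf <- length(hc$labels)
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    child <- function(j) {
      bl <- h - if (j > 0) hc$height[j] else 0
      paste0(build(j), ":", format(bl, digits = 8))
    }
    paste0("(", child(kids[1]), ",", child(kids[2]), ")")
  }
  writeLines(paste0(build(nrow(hc$merge)), ";"), path)
  invisible(path)
}
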
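# The CNA filtering cascade: population-CNV filtering, subtraction of
# alterations seen in non-progressive samples, recurrent-region construction
# by single-linkage reciprocal-overlap clustering, sequential-recurrence
# classification across graded lesion series, and cohort frequency tables.

#' Remove calls matching population copy-number variants
#'
#' A call is removed iff some catalog entry of the same direction overlaps it
#' at reciprocal overlap `>= min_reciprocal_overlap` and that entry's
#' population frequency exceeds `max_population_frequency`. Catalog variants
#' that are "very rare or absent" in the general population (frequency at or
#' below the cap) do not trigger removal.
#'
#' @param calls non-neutral calls data frame (see [call_segments()]).
#' @param catalog a [cnv_catalog()].
#' @param min_reciprocal_overlap matching threshold, default 0.5.
#' @param max_population_frequency rarity cap, default 0.01.
#' @return list with `kept` and `removed` (disjoint, union = input) and a
#'   `report` row (`n_input`, `n_kept`, `n_removed`).
#' @export
filter_population_cnvs <- function(calls, catalog,
                                   min_reciprocal_overlap = 0.5,
                                   max_population_frequency = 0.01) {
  stopifnot(!"neutral" %in% calls$direction)
  common <- catalog[catalog$frequency > max_population_frequency, ,
                    drop = FALSE]
  hits <- .ro_hits(calls, common, min_reciprocal_overlap)
  rm_idx <- sort(unique(hits$query_idx))
  kept <- calls[setdiff(seq_len(nrow(calls)), rm_idx), , drop = FALSE]
  removed <- calls[rm_idx, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed,
       report = data.frame(n_input = nrow(calls), n_kept = nrow(kept),
                           n_removed = nrow(removed)))
}

#' Subtract non-progressive alterations from progressive calls
#'
#' A progressive call is removed iff any non-progressive call of the same
#' direction overlaps it at reciprocal overlap `>= min_reciprocal_overlap`.
#' Both call sets are expected to be post-CNV-filter.
#'
#' @param progressive_calls,nonprogressive_calls call data frames.
#' @param min_reciprocal_overlap matching threshold, default 0.5.
#' @return list with `kept`, `removed` and a `report` row.
#' @export
subtract_group_cnas <- function(progressive_calls, nonprogressive_calls,
                                min_reciprocal_overlap = 0.5) {
  hits <- .ro_hits(progressive_calls, nonprogressive_calls,
                   min_reciprocal_overlap)
  rm_idx <- sort(unique(hits$query_idx))
  kept <- progressive_calls[setdiff(seq_len(nrow(progressive_calls)), rm_idx),
                            , drop = FALSE]
  removed <- progressive_calls[rm_idx, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed,
       report = data.frame(n_input = nrow(progressive_calls),
                           n_kept = nrow(kept), n_removed = nrow(removed)))
}

# Union-find with path compression; returns component labels.
.union_find <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (e in seq_along(edges_i)) {
    ri <- find(edges_i[e]); rj <- find(edges_j[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

# Minimal region of a cluster of same-chromosome intervals: the global
# intersection when non-empty; otherwise the leftmost maximal run at the
# deepest coverage depth (single-linkage chains can have empty global
# intersection, but a depth core always exists).
.minimal_region <- function(start, end) {
  lo <- max(start); hi <- min(end)
  if (lo < hi) return(c(lo, hi))
  pts <- sort(unique(c(start, end)))
  depth <- vapply(seq_len(length(pts) - 1L), function(i) {
    sum(start <= pts[i] & end >= pts[i + 1L])
  }, numeric(1))
  i <- which.max(depth)
  j <- i
  while (j < length(depth) && depth[j + 1L] == depth[i]) j <- j + 1L
  c(pts[i], pts[j + 1L])
}

#' Build recurrent regions from per-sample calls
#'
#' Same-direction calls are single-linkage clustered: two calls join the same
#' cluster iff their reciprocal overlap is at least the threshold (chains are
#' followed transitively). Each cluster yields one region: `interval` is the
#' union span of its members, `minimal_region` their common core (global
#' intersection, or the deepest-coverage sub-interval when a chain's global
#' intersection is empty), `samples_present` the contributing samples, and
#' `frequency` the fraction of the denominator group carrying the region.
#'
#' @param calls non-neutral calls from two or more samples.
#' @param metas a `sample_meta` data frame (defines the denominator group).
#' @param min_reciprocal_overlap clustering threshold, default 0.5.
#' @param group groups forming the frequency denominator; default
#'   `c("PL", "OSCC")`.
#' @return data frame of regions: `chrom`, `start`, `end`, `direction`,
#'   `min_start`, `min_end`, `n_present`, `frequency`, and a list-column
#'   `samples_present`.
#' @export
build_recurrent_regions <- function(calls, metas,
                                    min_reciprocal_overlap = 0.5,
                                    group = c("PL", "OSCC")) {
  if (length(unique(calls$sample_id)) < 2L) {
    stop("recurrent regions need calls from >= 2 samples")
  }
  denom <- metas$sample_id[metas$group %in% group]
  n_group <- length(denom)
  if (n_group == 0L) stop("empty denominator group")
  hits <- .ro_hits(calls, calls, min_reciprocal_overlap)
  hits <- hits[hits$query_idx < hits$subject_idx, , drop = FALSE]
  comp <- .union_find(nrow(calls), hits$query_idx, hits$subject_idx)
  idx <- split(seq_len(nrow(calls)), comp)
  rows <- lapply(idx, function(ii) {
    s <- calls$start[ii]; e <- calls$end[ii]
    mr <- .minimal_region(s, e)
    samples <- sort(unique(calls$sample_id[ii]))
    data.frame(chrom = calls$chrom[ii[1]], start = min(s), end = max(e),
               direction = calls$direction[ii[1]],
               min_start = mr[1], min_end = mr[2],
               n_present = length(intersect(samples, denom)),
               frequency = length(intersect(samples, denom)) / n_group,
               samples_present = I(list(samples)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(.chrom_rank(out$chrom), out$start, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify regions by sequential recurrence within progressive patients
#'
#' For each progressive patient (patients in groups `PL`/`OSCC` sharing a
#' `patient_id` with at least one OSCC sample), a region is
#' `in_OSCC_and_preceding_OPML` iff it is present in one of the patient's
#' OSCC samples and in at least one lesion with a smaller `lesion_order`;
#' it is `in_all_sequential_samples` iff present in every sample of the
#' series. Presence of a region in a sample means the sample contributed at
#' least one call to the region's cluster. Patients without an OSCC sample
#' are skipped with a warning.
#'
#' @param regions output of [build_recurrent_regions()].
#' @param metas a `sample_meta` data frame.
#' @return list with `per_patient` (long data frame: region index, patient,
#'   classification), `region_class` (one classification per region: the
#'   strongest across patients, `in_all_sequential_samples` >
#'   `in_OSCC_and_preceding_OPML` > `other`) and `summary` (number of
#'   regions whose best classification is each category, plus
#'   `n_patients_in_all` / `n_patients_osc_preceding` per region inside
#'   `region_class`).
#' @export
sequential_recurrence <- function(regions, metas) {
  prog <- metas[metas$group %in% c("PL", "OSCC"), , drop = FALSE]
  patients <- unique(prog$patient_id)
  keep <- vapply(patients, function(p) {
    any(prog$group[prog$patient_id == p] == "OSCC")
  }, logical(1))
  if (any(!keep)) {
    warning("progressive patient(s) without an OSCC sample skipped: ",
            paste(patients[!keep], collapse = ","))
  }
  patients <- patients[keep]
  per <- list()
  for (p in patients) {
    ser <- prog[prog$patient_id == p, , drop = FALSE]
    ser <- ser[order(ser$lesion_order), , drop = FALSE]
    osc <- ser[ser$group == "OSCC", , drop = FALSE]
    for (r in seq_len(nrow(regions))) {
      present <- ser$sample_id %in% regions$samples_present[[r]]
      in_all <- all(present)
      in_op <- any(vapply(seq_len(nrow(osc)), function(k) {
        oi <- match(osc$sample_id[k], ser$sample_id)
        present[oi] && any(present[ser$lesion_order < osc$lesion_order[k]])
      }, logical(1)))
      cls <- if (in_all) "in_all_sequential_samples"
             else if (in_op) "in_OSCC_and_preceding_OPML"
             else "other"
      per[[length(per) + 1L]] <- data.frame(region = r, patient_id = p,
                                            classification = cls,
                                            stringsAsFactors = FALSE)
    }
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(region = integer(), patient_id = character(),
               classification = character(), stringsAsFactors = FALSE)
  lvl <- c("other", "in_OSCC_and_preceding_OPML", "in_all_sequential_samples")
  region_class <- data.frame(
    region = seq_len(nrow(regions)),
    classification = vapply(seq_len(nrow(regions)), function(r) {
      cl <- per$classification[per$region == r]
      if (length(cl) == 0L) return("other")
      lvl[max(match(cl, lvl))]
    }, character(1)),
    n_patients_in_all = vapply(seq_len(nrow(regions)), function(r) {
      sum(per$classification[per$region == r] == "in_all_sequential_samples")
    }, numeric(1)),
    n_patients_osc_preceding = vapply(seq_len(nrow(regions)), function(r) {
      sum(per$classification[per$region == r] %in% lvl[2:3])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  list(per_patient = per, region_class = region_class,
       summary = table(factor(region_class$classification, levels = lvl)))
}

#' Cohort frequency table of recurrent regions
#'
#' One row per region present in at least one sample of the group, sorted by
#' percent descending; `percent = 100 * n_present / n_group`.
#'
#' @param regions output of [build_recurrent_regions()].
#' @param metas a `sample_meta` data frame.
#' @param group groups forming the denominator; default `c("PL", "OSCC")`.
#' @return data frame with `chrom`, `start`, `end`, `direction`,
#'   `n_present`, `n_group`, `percent`.
#' @export
frequency_table <- function(regions, metas, group = c("PL", "OSCC")) {
  denom <- metas$sample_id[metas$group %in% group]
  if (length(denom) == 0L) stop("empty group")
  n_present <- vapply(regions$samples_present,
                      function(s) length(intersect(s, denom)), numeric(1))
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, direction = regions$direction,
                    n_present = n_present, n_group = length(denom),
                    percent = 100 * n_present / length(denom),
                    stringsAsFactors = FALSE)
  out <- out[out$n_present > 0, , drop = FALSE]
  out <- out[order(-out$percent, .chrom_rank(out$chrom), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate regions with overlapping genes and drop gene-less regions
#'
#' When a gene annotation is supplied (BED4: chrom, start, end, name), each
#' region gains a `genes` column listing overlapping gene names
#' (comma-joined) and regions overlapping no known gene are removed, per the
#' analysis design. With `genes = NULL` the exclusion is skipped with a
#' message and the input is returned unchanged.
#'
#' @param regions output of [build_recurrent_regions()].
#' @param genes data frame with `chrom`, `start`, `end`, `name` (e.g. from
#'   [read_genes_bed()]), or `NULL`.
#' @return the annotated (and possibly reduced) regions data frame.
#' @export
annotate_genes <- function(regions, genes = NULL) {
  if (is.null(genes)) {
    message("no gene annotation supplied; gene-less region exclusion skipped")
    return(regions)
  }
  hits <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- genes$chrom == regions$chrom[i] & genes$start < regions$end[i] &
      genes$end > regions$start[i]
    genes$name[sel]
  })
  regions$genes <- vapply(hits, paste, character(1), collapse = ",")
  out <- regions[lengths(hits) > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene annotation BED4 file
#' @param path tab-separated file: chrom, start, end, gene name; no header.
#' @return data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_genes_bed <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("gene annotation must be BED4")
  data.frame(chrom = normalize_chrom(raw[[1]]), start = as.numeric(raw[[2]]),
             end = as.numeric(raw[[3]]), name = as.character(raw[[4]]),
             stringsAsFactors = FALSE)
}

#' Find regions containing a genomic locus
#'
#' Returns the regions whose interval overlaps the query (half-open
#' semantics: a point at a region's `end` coordinate is outside it).
#'
#' @param point a [genomic_interval()] (length >= 1 bp).
#' @param regions output of [build_recurrent_regions()].
#' @return the subset of `regions` overlapping `point`.
#' @export
locus_in_regions <- function(point, regions) {
  stopifnot(inherits(point, "genomic_interval"))
  hit <- regions$chrom == point$chrom & regions$start < point$end &
    regions$end > point$start
  out <- regions[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
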
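# Genomic-interval primitives. All coordinates are 0-based half-open [start, end)
# on "chr"-prefixed autosome labels; probe positions are length-1 intervals.

.AUTOSOMES <- paste0("chr", 1:22)
.GRADE_LEVELS <- c("non_dysplastic", "mild", "moderate", "severe_or_CIS", "carcinoma")
.GROUP_LEVELS <- c("PL", "NPL", "OSCC", "NORMAL")

#' Normalize chromosome labels
#'
#' Bare labels (`"1"`) are given a `"chr"` prefix; sex chromosomes and
#' unplaced contigs are returned as-is so callers can drop them.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @keywords internal
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

#' Test for recognized autosome labels
#' @param chrom character vector (normalized or not).
#' @return logical vector.
#' @keywords internal
is_autosome <- function(chrom) normalize_chrom(chrom) %in% .AUTOSOMES

#' Construct a genomic interval
#'
#' Coordinates are 0-based half-open; only autosomes `chr1..chr22` are
#' accepted (the analysis excludes sex chromosomes at ingest).
#'
#' @param chrom chromosome label, e.g. `"chr1"` (bare `"1"` is normalized).
#' @param start 0-based inclusive start (bp).
#' @param end exclusive end (bp); must satisfy `start < end`.
#' @return an object of class `genomic_interval`: a list with elements
#'   `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  if (length(chrom) != 1L || !is_autosome(chrom)) {
    stop("chromosome must be a single autosome label (chr1..chr22), got: ",
         paste(chrom, collapse = ","))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start >= end) {
    stop("invalid interval: require start < end, got [", start, ", ", end, ")")
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%s, %s)\n", x$chrom, format(x$start), format(x$end)))
  invisible(x)
}

.interval_fields <- function(x) {
  if (inherits(x, "genomic_interval")) {
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    data.frame(chrom = normalize_chrom(x$chrom), start = as.numeric(x$start),
               end = as.numeric(x$end), stringsAsFactors = FALSE)
  } else {
    stop("expected a genomic_interval or a data.frame with chrom/start/end")
  }
}

#' Reciprocal overlap of two genomic intervals
#'
#' Returns `min(|a intersect b| / |a|, |a intersect b| / |b|)`, the standard
#' symmetric matching criterion for CNV/CNA intervals; 0 when the intervals
#' are on different chromosomes or do not overlap. Vectorized over rows when
#' given data frames (shorter argument recycled if length 1).
#'
#' @param a,b `genomic_interval` objects or data frames with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return numeric vector of proportions in \[0, 1\].
#' @examples
#' reciprocal_overlap(genomic_interval("chr1", 100, 200),
#'                    genomic_interval("chr1", 150, 250))  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  a <- .interval_fields(a); b <- .interval_fields(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  stopifnot(nrow(a) == nrow(b))
  inter <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ro <- pmin(inter / (a$end - a$start), inter / (b$end - b$start))
  ro[a$chrom != b$chrom] <- 0
  ro
}

# Reciprocal-overlap hits between two interval tables, restricted to pairs of
# the same direction when both carry a `direction` column. Candidate pairs come
# from IRanges::findOverlaps; the reciprocal criterion is applied on top.
# Returns a data.frame of (query_idx, subject_idx, ro).
.ro_hits <- function(query, subject, min_ro) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query_idx = integer(), subject_idx = integer(),
                      ro = numeric()))
  }
  q <- .interval_fields(query); s <- .interval_fields(subject)
  # IRanges is 1-based closed; [start, end) maps to start+1 .. end
  qr <- split(seq_len(nrow(q)), q$chrom)
  out <- vector("list", length(qr))
  for (i in seq_along(qr)) {
    chr <- names(qr)[i]
    qi <- qr[[i]]
    si <- which(s$chrom == chr)
    if (length(si) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q$start[qi] + 1L, q$end[qi]),
      IRanges::IRanges(s$start[si] + 1L, s$end[si]))
    if (length(hits) == 0L) next
    qidx <- qi[S4Vectors::queryHits(hits)]
    sidx <- si[S4Vectors::subjectHits(hits)]
    ro <- reciprocal_overlap(q[qidx, , drop = FALSE], s[sidx, , drop = FALSE])
    keep <- ro >= min_ro
    if ("direction" %in% names(query) && "direction" %in% names(subject)) {
      keep <- keep & (query$direction[qidx] == subject$direction[sidx])
    }
    out[[i]] <- data.frame(query_idx = qidx[keep], subject_idx = sidx[keep],
                           ro = ro[keep])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(query_idx = integer(), subject_idx = integer(),
                      ro = numeric()))
  }
  do.call(rbind, out)
}
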
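# Readers and writers for every plain-text file the pipeline touches:
# probe TSVs, the sample sheet, call/region BED, and the population CNV catalog.

#' Construct a probe-level log2-ratio profile
#'
#' A `probe_profile` is one sample's ordered autosomal measurements: a
#' data frame with columns `chrom`, `pos` (0-based probe position, bp) and
#' `log2_ratio`, sorted by chromosome then position, with the sample id
#' attached as an attribute.
#'
#' @param chrom,pos,log2_ratio parallel vectors of probe measurements.
#' @param sample_id sample label.
#' @param sort sort probes by (chromosome, position)? Default `TRUE`.
#' @return a `probe_profile` data frame.
#' @export
probe_profile <- function(chrom, pos, log2_ratio, sample_id, sort = TRUE) {
  chrom <- normalize_chrom(chrom)
  if (!all(is_autosome(chrom))) stop("probe_profile accepts autosomes only")
  pos <- as.numeric(pos); log2_ratio <- as.numeric(log2_ratio)
  if (any(!is.finite(log2_ratio))) stop("log2_ratio must be finite")
  df <- data.frame(chrom = chrom, pos = pos, log2_ratio = log2_ratio,
                   stringsAsFactors = FALSE)
  if (sort) {
    df <- df[order(.chrom_rank(df$chrom), df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  incr <- tapply(df$pos, factor(df$chrom, levels = unique(df$chrom)),
                 function(p) all(diff(p) > 0))
  if (nrow(df) > 0L && !all(unlist(incr))) {
    stop("probe positions must be strictly increasing within chromosome")
  }
  attr(df, "sample_id") <- as.character(sample_id)
  class(df) <- c("probe_profile", "data.frame")
  df
}

.chrom_rank <- function(chrom) match(chrom, .AUTOSOMES)

#' Sample id of a probe profile
#' @param profile a `probe_profile`.
#' @return character scalar.
#' @export
sample_id <- function(profile) attr(profile, "sample_id")

#' Read a probe-level aCGH profile from a tab-separated file
#'
#' The file must have header columns `chromosome`, `position`, `log2_ratio`.
#' Sex-chromosome rows are dropped with a message reporting the count
#' (sex chromosomes are excluded from the analysis at ingest); remaining
#' probes are sorted by (chromosome, position).
#'
#' @param path path to the TSV file.
#' @param sample_id sample label to attach; defaults to the file base name.
#' @return a [probe_profile()].
#' @export
read_probe_profile <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("chromosome", "position", "log2_ratio")
  if (!all(need %in% names(raw))) {
    stop("probe file ", path, " must have header columns: ",
         paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  lr <- suppressWarnings(as.numeric(raw$log2_ratio))
  bad <- which(!is.finite(pos) | !is.finite(lr) | raw$chromosome == "")
  if (length(bad) > 0L) {
    stop("malformed probe row at line ", bad[1] + 1L, " of ", path)
  }
  chrom <- normalize_chrom(raw$chromosome)
  keep <- is_autosome(chrom)
  if (any(!keep)) {
    message("read_probe_profile: dropped ", sum(!keep),
            " non-autosomal probe(s) from ", basename(path))
  }
  if (!any(keep)) stop("no autosomal probes in ", path)
  probe_profile(chrom[keep], pos[keep], lr[keep], sample_id = sample_id)
}

#' Write a probe profile as a tab-separated file
#' @param profile a [probe_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_profile <- function(profile, path) {
  out <- data.frame(chromosome = profile$chrom, position = profile$pos,
                    log2_ratio = profile$log2_ratio)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample sheet ----------------------------------------------------------

#' Map free-text histology labels onto the grade ladder
#'
#' Recognizes the grades used for oral premalignant lesions. Severe dysplasia
#' and carcinoma in situ form a single level (`severe_or_CIS`); mixed labels
#' joined by `+` are assigned the higher grade. Canonical level names pass
#' through unchanged.
#'
#' @param x character vector of diagnosis strings or canonical grade levels.
#' @return character vector of levels among
#'   `non_dysplastic, mild, moderate, severe_or_CIS, carcinoma`.
#' @export
parse_grade <- function(x) {
  one <- function(lbl) {
    if (lbl %in% .GRADE_LEVELS) return(lbl)
    parts <- trimws(strsplit(lbl, "\\+")[[1]])
    rank <- vapply(parts, function(p) {
      p <- tolower(p)
      if (grepl("carcinoma *in *situ", p)) return(4L)
      if (grepl("invasive|oscc|\\bscc\\b|carcinoma", p)) return(5L)
      # keratosis/hyperplasia are non-dysplastic even when an adjective such
      # as "mild" modifies them ("Mild squamous hyperplasia")
      if (grepl("keratosis|hyperplasia|non[-_ ]?dysplastic", p)) return(1L)
      if (grepl("severe", p)) return(4L)
      if (grepl("moderate", p)) return(3L)
      if (grepl("mild", p)) return(2L)
      NA_integer_
    }, integer(1))
    if (all(is.na(rank))) stop("unrecognized histology grade: '", lbl, "'")
    .GRADE_LEVELS[max(rank, na.rm = TRUE)]
  }
  vapply(as.character(x), one, character(1), USE.NAMES = FALSE)
}

#' Read and validate a sample sheet
#'
#' CSV with columns `sample_id`, `patient_id`, `group`
#' (`PL`/`NPL`/`OSCC`/`NORMAL`), `grade` (canonical level or free-text
#' diagnosis, parsed by [parse_grade()]), `lesion_order` (integer rank of the
#' biopsy within its patient) and `tobacco` (`yes`/`no`/`unknown`).
#'
#' @param path path to the CSV.
#' @return a `sample_meta` data frame.
#' @export
read_sample_sheet <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "patient_id", "group", "grade", "lesion_order",
            "tobacco")
  if (!all(need %in% names(raw))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  sample_meta(sample_id = raw$sample_id, patient_id = raw$patient_id,
              group = raw$group, grade = raw$grade,
              lesion_order = raw$lesion_order, tobacco = raw$tobacco)
}

#' Construct validated sample metadata
#'
#' @param sample_id,patient_id,group,grade,lesion_order,tobacco parallel
#'   vectors; `grade` may be free-text diagnoses (see [parse_grade()]).
#' @return a `sample_meta` data frame.
#' @export
sample_meta <- function(sample_id, patient_id, group, grade, lesion_order,
                        tobacco = "unknown") {
  df <- data.frame(sample_id = as.character(sample_id),
                   patient_id = as.character(patient_id),
                   group = as.character(group),
                   grade = parse_grade(grade),
                   lesion_order = as.integer(lesion_order),
                   tobacco = tolower(as.character(tobacco)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ","))
  }
  if (!all(df$group %in% .GROUP_LEVELS)) {
    stop("group must be one of ", paste(.GROUP_LEVELS, collapse = "/"))
  }
  if (!all(df$tobacco %in% c("yes", "no", "unknown"))) {
    stop("tobacco must be yes/no/unknown")
  }
  bad <- df$group == "OSCC" & df$grade != "carcinoma"
  if (any(bad)) {
    stop("OSCC sample(s) with non-carcinoma grade: ",
         paste(df$sample_id[bad], collapse = ","))
  }
  dup_ord <- unlist(tapply(df$lesion_order, df$patient_id,
                           function(o) any(duplicated(o))))
  if (any(dup_ord)) stop("lesion_order must be unique within patient")
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Write a sample sheet CSV
#' @param metas a `sample_meta` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(metas, path) {
  utils::write.csv(as.data.frame(metas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- call BED --------------------------------------------------------------

#' Write CNA calls as BED5+
#'
#' Columns: chrom, start, end, name (`sample:direction`), score
#' (`round(mean_log2 * 1000)`), direction, n_markers, sd_log2. Coordinates
#' are 0-based half-open. No header line.
#'
#' @param calls a calls data frame (see [call_segments()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- data.frame(
    chrom = calls$chrom,
    start = format(calls$start, scientific = FALSE, trim = TRUE),
    end = format(calls$end, scientific = FALSE, trim = TRUE),
    name = paste0(calls$sample_id, ":", calls$direction),
    score = round(calls$mean_log2 * 1000),
    direction = calls$direction,
    n_markers = calls$n_markers,
    sd_log2 = sprintf("%.6g", calls$sd_log2))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CNA calls from BED5+ written by [write_calls_bed()]
#' @param path path to the BED file.
#' @return a calls data frame; `mean_log2` is recovered to 3 decimals.
#' @export
read_calls_bed <- function(path) {
  if (file.size(path) == 0) return(.empty_calls())
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 7L) stop("call BED must have >= 7 columns")
  names(raw)[1:7] <- c("chrom", "start", "end", "name", "score", "direction",
                       "n_markers")
  data.frame(
    sample_id = sub(":[^:]*$", "", raw$name),
    chrom = normalize_chrom(raw$chrom),
    start = as.numeric(raw$start), end = as.numeric(raw$end),
    mean_log2 = raw$score / 1000,
    sd_log2 = if (ncol(raw) >= 8L) as.numeric(raw[[8]]) else NA_real_,
    n_markers = as.integer(raw$n_markers),
    direction = raw$direction,
    linear_ratio = 2^(raw$score / 1000),
    stringsAsFactors = FALSE)
}

.empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), mean_log2 = numeric(), sd_log2 = numeric(),
             n_markers = integer(), direction = character(),
             linear_ratio = numeric(), stringsAsFactors = FALSE)
}

# ---- CNV catalog -----------------------------------------------------------

#' Read a population CNV catalog (BED4+)
#'
#' Tab-separated, no header: chrom, start, end, direction (`gain`/`loss`)
#' and optionally population frequency in \[0, 1\]. Rows without a frequency
#' are assigned 1.0: bare presence in a population catalog is taken to mean
#' the variant is common enough to filter.
#'
#' @param path path to the BED file.
#' @return a data frame with columns `chrom`, `start`, `end`, `direction`,
#'   `frequency`.
#' @export
read_cnv_catalog <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("CNV catalog must be BED4+ (chrom start end direction)")
  cnv_catalog(chrom = raw[[1]], start = raw[[2]], end = raw[[3]],
              direction = raw[[4]],
              frequency = if (ncol(raw) >= 5L) as.numeric(raw[[5]]) else 1.0)
}

#' Construct a validated CNV catalog
#' @param chrom,start,end,direction,frequency parallel vectors.
#' @return a data frame with class `cnv_catalog`.
#' @export
cnv_catalog <- function(chrom, start, end, direction, frequency = 1.0) {
  df <- data.frame(chrom = normalize_chrom(chrom), start = as.numeric(start),
                   end = as.numeric(end), direction = as.character(direction),
                   frequency = as.numeric(frequency), stringsAsFactors = FALSE)
  stopifnot(all(is_autosome(df$chrom)), all(df$start < df$end),
            all(df$direction %in% c("gain", "loss")),
            all(df$frequency >= 0 & df$frequency <= 1))
  class(df) <- c("cnv_catalog", "data.frame")
  df
}

#' Write a CNV catalog as BED5
#' @param catalog a [cnv_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_catalog <- function(catalog, path) {
  out <- data.frame(catalog$chrom,
                    format(catalog$start, scientific = FALSE, trim = TRUE),
                    format(catalog$end, scientific = FALSE, trim = TRUE),
                    catalog$direction, catalog$frequency)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- cytobands (optional display annotation) -------------------------------

#' Read a UCSC-layout cytoband file
#'
#' Five tab-separated columns without header: chrom, start, end, band name
#' (e.g. `p36.1`), Giemsa stain. Used only to decorate regions with band
#' labels; coordinates remain the unit of analysis.
#'
#' @param path path to the cytoband file.
#' @return data frame with columns `chrom`, `start`, `end`, `band`.
#' @export
read_cytoband <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(chrom = normalize_chrom(raw[[1]]), start = as.numeric(raw[[2]]),
             end = as.numeric(raw[[3]]), band = as.character(raw[[4]]),
             stringsAsFactors = FALSE)
}

#' Annotate intervals with cytoband labels
#' @param x data frame with `chrom`, `start`, `end`.
#' @param cytoband output of [read_cytoband()].
#' @return `x` with an added `band` column (`chrN` prefix stripped to the
#'   conventional `1p36.1` style; multiple overlapped bands joined by `-`).
#' @export
annotate_bands <- function(x, cytoband) {
  lbl <- vapply(seq_len(nrow(x)), function(i) {
    hit <- cytoband$chrom == x$chrom[i] & cytoband$start < x$end[i] &
      cytoband$end > x$start[i]
    if (!any(hit)) return(NA_character_)
    bands <- cytoband$band[hit]
    num <- sub("^chr", "", x$chrom[i])
    if (length(bands) == 1L) paste0(num, bands)
    else paste0(num, bands[1], "-", num, bands[length(bands)])
  }, character(1))
  x$band <- lbl
  x
}
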
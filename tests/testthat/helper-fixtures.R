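# Programmatic fixtures shared across test files.

# A single-chromosome profile from a numeric vector, probes 7 kb apart.
step_profile <- function(x, chrom = "chr1", sample_id = "S1",
                         spacing = 7000) {
  probe_profile(rep(chrom, length(x)), (seq_along(x) - 1) * spacing, x,
                sample_id = sample_id, sort = FALSE)
}

# Desk-scale-but-small cohort configuration for fast construction tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_progressive_patients = 2L, lesions_per_patient = 3L,
         n_nonprogressive = 2L, n_normal = 1L,
         probes_per_chromosome = 600L, n_core_cnas = 2L,
         catalog_size = 4L, cna_min_probes = 30L,
         cna_max_probes = 40L, seed = 11L),
    list(...))
  do.call(cohort_config, args)
}

# Random non-neutral call table spread over samples and chromosomes.
random_calls <- function(n, n_samples = 5L, chroms = paste0("chr", 1:4),
                         max_pos = 5e6) {
  start <- round(stats::runif(n, 0, max_pos - 2e5))
  len <- round(stats::runif(n, 2e4, 2e5))
  dir <- sample(c("gain", "loss"), n, replace = TRUE)
  ml <- ifelse(dir == "gain", 0.58, -1.0)
  data.frame(sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n,
                                replace = TRUE),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             mean_log2 = ml, sd_log2 = 0.1,
             n_markers = pmax(10L, as.integer(len / 7000)),
             direction = dir, linear_ratio = 2^ml,
             stringsAsFactors = FALSE)
}

# Minimal sample sheet for n progressive samples in one patient plus extras.
toy_metas <- function() {
  sample_meta(
    sample_id = c("L1", "L2", "T", "NP1", "N1"),
    patient_id = c("P1", "P1", "P1", "NP1", "N1"),
    group = c("PL", "PL", "OSCC", "NPL", "NORMAL"),
    grade = c("mild", "severe_or_CIS", "carcinoma", "mild", "non_dysplastic"),
    lesion_order = c(1L, 2L, 3L, 1L, 1L),
    tobacco = c("yes", "yes", "yes", "no", "unknown"))
}
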
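# Synthetic cohort generator: sequential same-patient lesion series with
# accumulating shared CNAs, non-progressive controls carrying only germline
# CNVs and private events, a population CNV catalog, and per-sample truth
# sets for every downstream test.
#
# The stated world emulates the study design: 5 progressive patients, each
# with a sequential series of graded lesions ending in carcinoma (25
# progressive samples), 5 non-progressive leukoplakia lesions, plus normal
# controls; a tiling array scaled to desk size (4 synthetic autosomes x
# 2000 probes at 7 kb median spacing); iid Gaussian probe noise.

.GRADE_LADDER <- c("non_dysplastic", "mild", "moderate", "severe_or_CIS",
                   "carcinoma")

#' Cohort simulation configuration
#'
#' Defaults encode the emulated study design and desk-scale array. Implanted
#' effect sizes are the single-copy values on the log2 scale: +0.58 for a
#' gain (3/2 copies) and -1.0 for a loss (1/2 copies), both callable in
#' expectation against the 1.15/0.85 linear-ratio thresholds.
#'
#' @param n_progressive_patients progressive patients, each contributing one
#'   sequential lesion series ending in carcinoma.
#' @param lesions_per_patient series length (2..5); the series walks the last
#'   `lesions_per_patient` rungs of the grade ladder
#'   `non_dysplastic, mild, moderate, severe_or_CIS, carcinoma`.
#' @param n_nonprogressive non-progressive leukoplakia samples.
#' @param n_normal normal control samples.
#' @param n_chromosomes,probes_per_chromosome,probe_spacing array geometry
#'   (synthetic autosomes `chr1..`, evenly spaced probes, spacing in bp).
#' @param noise_sd iid Gaussian probe noise SD on the log2 scale.
#' @param n_core_cnas cohort-level progression-core CNAs: present in every
#'   lesion of every progressive series (shared across patients, so they
#'   form the recurrent progression regions). The default keeps the shared
#'   progression burden larger than the per-sample patient-specific burden
#'   (up to 4 grade-acquired + 1 private + 2 germline events), mirroring a
#'   cohort whose most frequent recurrent regions span half to all of the
#'   progressive samples.
#' @param n_grade_acquired_per_step CNAs acquired by a patient at each grade
#'   step after the first and retained thereafter (monotone presence), drawn
#'   without replacement per patient from a cohort-level pool of recurrent
#'   progression regions (below).
#' @param n_acquired_pool size of the shared pool of acquirable progression
#'   regions. Different patients draw from the same pool, so acquired
#'   regions recur in a subset of patients, reproducing the mid-range
#'   (roughly 40-80%) cohort frequencies that recurrent non-core regions
#'   show; a pool a bit larger than one patient's total draws keeps the
#'   overlap partial.
#' @param n_private per-sample one-off CNAs (any group except normals).
#' @param n_popcnv_per_sample germline CNVs per individual, drawn from the
#'   catalog; shared by all lesions of a patient.
#' @param catalog_size population CNV catalog entries.
#' @param gain_log2,loss_log2 implanted single-copy effect sizes (log2).
#' @param cna_min_probes,cna_max_probes implanted event lengths in probes
#'   (uniform); the default minimum is 3x the 10-marker segmentation floor.
#' @param seed RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_progressive_patients = 5L,
                          lesions_per_patient = 5L,
                          n_nonprogressive = 5L,
                          n_normal = 3L,
                          n_chromosomes = 4L,
                          probes_per_chromosome = 2000L,
                          probe_spacing = 7000,
                          noise_sd = 0.1,
                          n_core_cnas = 6L,
                          n_grade_acquired_per_step = 1L,
                          n_acquired_pool = 8L,
                          n_private = 1L,
                          n_popcnv_per_sample = 2L,
                          catalog_size = 20L,
                          gain_log2 = 0.58,
                          loss_log2 = -1.0,
                          cna_min_probes = 30L,
                          cna_max_probes = 50L,
                          seed = 1L) {
  cfg <- list(n_progressive_patients = as.integer(n_progressive_patients),
              lesions_per_patient = as.integer(lesions_per_patient),
              n_nonprogressive = as.integer(n_nonprogressive),
              n_normal = as.integer(n_normal),
              n_chromosomes = as.integer(n_chromosomes),
              probes_per_chromosome = as.integer(probes_per_chromosome),
              probe_spacing = as.numeric(probe_spacing),
              noise_sd = as.numeric(noise_sd),
              n_core_cnas = as.integer(n_core_cnas),
              n_grade_acquired_per_step = as.integer(n_grade_acquired_per_step),
              n_acquired_pool = as.integer(n_acquired_pool),
              n_private = as.integer(n_private),
              n_popcnv_per_sample = as.integer(n_popcnv_per_sample),
              catalog_size = as.integer(catalog_size),
              gain_log2 = as.numeric(gain_log2),
              loss_log2 = as.numeric(loss_log2),
              cna_min_probes = as.integer(cna_min_probes),
              cna_max_probes = as.integer(cna_max_probes),
              seed = as.integer(seed))
  counts <- cfg[grepl("^n_|_size$|probes_per", names(cfg))]
  stopifnot(all(unlist(counts) >= 0), cfg$noise_sd >= 0,
            cfg$lesions_per_patient >= 2L, cfg$lesions_per_patient <= 5L,
            cfg$n_chromosomes >= 1L, cfg$n_chromosomes <= 22L,
            cfg$cna_min_probes >= 2L,
            cfg$cna_min_probes <= cfg$cna_max_probes,
            cfg$n_acquired_pool >=
              (cfg$lesions_per_patient - 1L) * cfg$n_grade_acquired_per_step,
            cfg$gain_log2 >= log2(1.15), cfg$loss_log2 <= log2(0.85))
  class(cfg) <- "cohort_config"
  cfg
}

# Draw `n` mutually non-overlapping intervals on the synthetic genome,
# avoiding the already-occupied list. The inter-event gap must exceed the
# 10-marker segmentation floor, otherwise adjacent events are unresolvable
# by construction (a sub-floor gap cannot form its own segment and the
# events merge into one call); 2x the floor keeps them cleanly separable.
# Returns a data.frame chrom/start/end plus probe index bounds, and updates
# the occupancy by reference convention (caller rebinds).
.draw_intervals <- function(n, config, occupied, gap = 20L) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(20000L)) {
      ch <- sample(chroms, 1L)
      len <- sample(config$cna_min_probes:config$cna_max_probes, 1L)
      if (config$probes_per_chromosome < len + 2L) next
      i1 <- sample.int(config$probes_per_chromosome - len + 1L, 1L)
      i2 <- i1 + len - 1L
      occ <- occupied[occupied$chrom == ch, , drop = FALSE]
      if (nrow(occ) == 0L ||
          all(i2 + gap < occ$p1 | i1 - gap > occ$p2)) {
        row <- data.frame(chrom = ch, p1 = i1, p2 = i2,
                          stringsAsFactors = FALSE)
        occupied <- rbind(occupied, row)
        res[[i]] <- row
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place ", n, " non-overlapping CNAs; ",
                      "config is too dense for the synthetic genome")
  }
  list(intervals = do.call(rbind, res), occupied = occupied)
}

.probe_bounds_to_bp <- function(df, config) {
  df$start <- (df$p1 - 1L) * config$probe_spacing
  df$end <- (df$p2 - 1L) * config$probe_spacing + 1
  df
}

.truth_row <- function(iv, direction, mean_log2, origin, sample_id) {
  if (nrow(iv) == 0L) return(.empty_truth())
  data.frame(sample_id = sample_id, chrom = iv$chrom, start = iv$start,
             end = iv$end, p1 = iv$p1, p2 = iv$p2, direction = direction,
             true_mean_log2 = mean_log2, origin = origin,
             stringsAsFactors = FALSE)
}

.empty_truth <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), p1 = integer(), p2 = integer(),
             direction = character(), true_mean_log2 = numeric(),
             origin = character(), stringsAsFactors = FALSE)
}

# Build one sample's probe profile from its truth rows.
.profile_from_truth <- function(truth, sid, config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  n <- config$probes_per_chromosome
  pos1 <- (seq_len(n) - 1L) * config$probe_spacing
  x <- rep(0, n * config$n_chromosomes)
  chrom <- rep(chroms, each = n)
  pos <- rep(pos1, config$n_chromosomes)
  if (nrow(truth) > 0L) {
    for (r in seq_len(nrow(truth))) {
      off <- (match(truth$chrom[r], chroms) - 1L) * n
      x[(off + truth$p1[r]):(off + truth$p2[r])] <- truth$true_mean_log2[r]
    }
  }
  if (config$noise_sd > 0) x <- x + stats::rnorm(length(x), 0, config$noise_sd)
  probe_profile(chrom, pos, x, sample_id = sid, sort = FALSE)
}

# Internal event-plan generator shared by simulate_cohort and
# simulate_patient_series: allocates disjoint interval pools.
.plan_events <- function(config) {
  occupied <- data.frame(chrom = character(), p1 = integer(), p2 = integer(),
                         stringsAsFactors = FALSE)
  draw <- function(n) {
    d <- .draw_intervals(n, config, occupied)
    occupied <<- d$occupied
    .probe_bounds_to_bp(d$intervals, config)
  }
  dir_for <- function(n) sample(c("gain", "loss"), n, replace = TRUE,
                                prob = c(0.8, 0.2))
  # progression events use the stated cohort composition (80% gains / 20%
  # losses) deterministically rather than by independent draws, so every
  # simulated cohort carries the stated gain/loss mix
  dir_fixed <- function(n) {
    k_loss <- round(0.2 * n)
    sample(rep(c("gain", "loss"), c(n - k_loss, k_loss)))
  }
  eff <- function(dir) ifelse(dir == "gain", config$gain_log2,
                              config$loss_log2)
  # population catalog: frequencies well above the 1% rarity cap so that
  # implanted germline events are removable by the filter
  catalog <- NULL
  if (config$catalog_size > 0L) {
    iv <- draw(config$catalog_size)
    d <- dir_for(config$catalog_size)
    catalog <- cnv_catalog(iv$chrom, iv$start, iv$end, d,
                           frequency = stats::runif(config$catalog_size,
                                                    0.05, 0.35))
    catalog$p1 <- iv$p1; catalog$p2 <- iv$p2
  }
  core <- NULL
  if (config$n_core_cnas > 0L) {
    iv <- draw(config$n_core_cnas)
    d <- dir_fixed(config$n_core_cnas)
    core <- cbind(iv, direction = d, true_mean_log2 = eff(d),
                  stringsAsFactors = FALSE)
  }
  # shared pool of acquirable progression regions (direction and effect are
  # properties of the region, identical in every patient that acquires it)
  acquired_pool <- NULL
  if (config$n_acquired_pool > 0L) {
    iv <- draw(config$n_acquired_pool)
    d <- dir_fixed(config$n_acquired_pool)
    acquired_pool <- cbind(iv, direction = d, true_mean_log2 = eff(d),
                           stringsAsFactors = FALSE)
  }
  list(catalog = catalog, core = core, acquired_pool = acquired_pool,
       draw = draw, dir_for = dir_for, eff = eff)
}

#' Simulate one progressive patient's sequential lesion series
#'
#' Generates one profile per grade step ending in carcinoma. Progression-core
#' CNAs (`core`) are present in every lesion; grade-acquired CNAs appear at
#' their grade of origin and persist (monotone presence); each lesion also
#' carries the patient's germline CNVs and its own private events. Probe
#' values are the true segment mean plus iid Gaussian noise.
#'
#' Uses the current global RNG state; seed before calling for
#' reproducibility ([simulate_cohort()] seeds from `config$seed`).
#'
#' @param config a [cohort_config()].
#' @param patient_id patient label.
#' @param core data frame of progression-core events (columns `chrom`,
#'   `start`, `end`, `p1`, `p2`, `direction`, `true_mean_log2`); pass `NULL`
#'   to draw a fresh set.
#' @param plan internal event plan (interval allocator); `NULL` for
#'   standalone use.
#' @return list with `profiles` (named list of [probe_profile()]),
#'   `metas` (a `sample_meta` data frame) and `truth` (data frame of
#'   implanted events per sample with an `origin` column).
#' @export
simulate_patient_series <- function(config, patient_id, core = NULL,
                                    plan = NULL) {
  if (is.null(plan)) plan <- .plan_events(config)
  if (is.null(core)) core <- plan$core
  grades <- utils::tail(.GRADE_LADDER, config$lesions_per_patient)
  k <- length(grades)
  # germline CNVs: same catalog entries in every lesion of this patient
  germ <- NULL
  if (!is.null(plan$catalog) && config$n_popcnv_per_sample > 0L) {
    idx <- sample.int(nrow(plan$catalog),
                      min(config$n_popcnv_per_sample, nrow(plan$catalog)))
    germ <- plan$catalog[idx, , drop = FALSE]
  }
  # grade-acquired events for steps 2..k: drawn without replacement (within
  # this patient) from the cohort-level pool of recurrent progression regions
  acq <- vector("list", k)
  avail <- seq_len(if (is.null(plan$acquired_pool)) 0L else
                     nrow(plan$acquired_pool))
  for (g in 2:k) {
    n_draw <- min(config$n_grade_acquired_per_step, length(avail))
    if (n_draw > 0L) {
      take <- if (length(avail) == 1L) avail else sample(avail, n_draw)
      acq[[g]] <- plan$acquired_pool[take, , drop = FALSE]
      avail <- setdiff(avail, take)
    }
  }
  profiles <- list(); truth <- list(); metas <- list()
  for (g in seq_len(k)) {
    sid <- paste0(patient_id, "_L", g)
    grp <- if (grades[g] == "carcinoma") "OSCC" else "PL"
    rows <- list()
    if (!is.null(core) && nrow(core) > 0L) {
      rows <- c(rows, list(.truth_row(core, core$direction,
                                      core$true_mean_log2,
                                      "progression_core", sid)))
    }
    for (h in 2:g) {
      if (g >= 2 && h <= g && !is.null(acq[[h]])) {
        rows <- c(rows, list(.truth_row(acq[[h]], acq[[h]]$direction,
                                        acq[[h]]$true_mean_log2,
                                        "grade_acquired", sid)))
      }
    }
    if (!is.null(germ)) {
      rows <- c(rows, list(.truth_row(
        germ, germ$direction,
        ifelse(germ$direction == "gain", config$gain_log2, config$loss_log2),
        "population_cnv", sid)))
    }
    if (config$n_private > 0L) {
      iv <- plan$draw(config$n_private)
      d <- plan$dir_for(config$n_private)
      rows <- c(rows, list(.truth_row(iv, d, plan$eff(d), "private", sid)))
    }
    tr <- if (length(rows)) do.call(rbind, rows) else .empty_truth()
    profiles[[sid]] <- .profile_from_truth(tr, sid, config)
    truth[[sid]] <- tr
    metas[[sid]] <- data.frame(sample_id = sid, patient_id = patient_id,
                               group = grp, grade = grades[g],
                               lesion_order = g, tobacco = "yes",
                               stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  metas <- do.call(rbind, metas); rownames(metas) <- NULL
  list(profiles = profiles,
       metas = sample_meta(metas$sample_id, metas$patient_id, metas$group,
                           metas$grade, metas$lesion_order, metas$tobacco),
       truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Progressive patients each contribute a sequential series ending in
#' carcinoma (see [simulate_patient_series()]); the progression-core events
#' are shared across all progressive patients, making them the cohort's
#' recurrent progression regions. Non-progressive and normal samples carry
#' only germline (catalog-matched) CNVs and — for non-progressive lesions —
#' private events. All implanted intervals across categories are mutually
#' non-overlapping, so subtraction and CNV filtering act only on their
#' intended targets. Deterministic under a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `profiles` (named list), `metas`, `truth`,
#'   `catalog` (a [cnv_catalog()]) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  plan <- .plan_events(config)
  profiles <- list(); truth <- list(); metas <- list()
  for (p in seq_len(config$n_progressive_patients)) {
    ser <- simulate_patient_series(config, sprintf("P%02d", p),
                                   core = plan$core, plan = plan)
    profiles <- c(profiles, ser$profiles)
    truth[[length(truth) + 1L]] <- ser$truth
    metas[[length(metas) + 1L]] <- as.data.frame(ser$metas)
  }
  ctrl <- function(prefix, n, group, grade, private) {
    for (i in seq_len(n)) {
      sid <- sprintf("%s%02d", prefix, i)
      rows <- list()
      if (!is.null(plan$catalog) && config$n_popcnv_per_sample > 0L) {
        idx <- sample.int(nrow(plan$catalog),
                          min(config$n_popcnv_per_sample, nrow(plan$catalog)))
        germ <- plan$catalog[idx, , drop = FALSE]
        rows <- c(rows, list(.truth_row(
          germ, germ$direction,
          ifelse(germ$direction == "gain", config$gain_log2,
                 config$loss_log2),
          "population_cnv", sid)))
      }
      if (private && config$n_private > 0L) {
        iv <- plan$draw(config$n_private)
        d <- plan$dir_for(config$n_private)
        rows <- c(rows, list(.truth_row(iv, d, plan$eff(d), "private", sid)))
      }
      tr <- if (length(rows)) do.call(rbind, rows) else .empty_truth()
      profiles[[sid]] <<- .profile_from_truth(tr, sid, config)
      truth[[length(truth) + 1L]] <<- tr
      metas[[length(metas) + 1L]] <<- data.frame(
        sample_id = sid, patient_id = sid, group = group, grade = grade,
        lesion_order = 1L, tobacco = "no", stringsAsFactors = FALSE)
    }
  }
  ctrl("NP", config$n_nonprogressive, "NPL", "mild", private = TRUE)
  ctrl("NORM", config$n_normal, "NORMAL", "non_dysplastic", private = FALSE)
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  metas <- do.call(rbind, metas)
  catalog <- plan$catalog
  if (!is.null(catalog)) catalog <- catalog[, c("chrom", "start", "end",
                                                "direction", "frequency")]
  else catalog <- cnv_catalog(character(), numeric(), numeric(), character(),
                              numeric())
  class(catalog) <- c("cnv_catalog", "data.frame")
  list(profiles = profiles,
       metas = sample_meta(metas$sample_id, metas$patient_id, metas$group,
                           metas$grade, metas$lesion_order, metas$tobacco),
       truth = truth, catalog = catalog, config = config)
}

#' Write a simulated cohort as a plain-text fixture directory
#'
#' Emits one probe TSV per sample, `samples.csv`, `catalog.bed` and
#' `truth.bed` (BED6: chrom, start, end, `sample:origin`, true mean log2
#' x1000, direction). Everything round-trips through the package readers.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$profiles)) {
    write_probe_profile(cohort$profiles[[sid]],
                        file.path(dir, paste0(sid, ".tsv")))
  }
  write_sample_sheet(cohort$metas, file.path(dir, "samples.csv"))
  write_cnv_catalog(cohort$catalog, file.path(dir, "catalog.bed"))
  tr <- cohort$truth
  out <- data.frame(tr$chrom,
                    format(tr$start, scientific = FALSE, trim = TRUE),
                    format(tr$end, scientific = FALSE, trim = TRUE),
                    paste0(tr$sample_id, ":", tr$origin),
                    round(tr$true_mean_log2 * 1000), tr$direction)
  utils::write.table(out, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory back into memory
#' @param dir directory written by [write_fixture()].
#' @return list with `profiles`, `metas`, `catalog`, `truth`.
#' @export
read_fixture <- function(dir) {
  metas <- read_sample_sheet(file.path(dir, "samples.csv"))
  profiles <- lapply(metas$sample_id, function(sid) {
    read_probe_profile(file.path(dir, paste0(sid, ".tsv")), sample_id = sid)
  })
  names(profiles) <- metas$sample_id
  tr <- utils::read.delim(file.path(dir, "truth.bed"), header = FALSE,
                          sep = "\t", stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = sub(":[^:]*$", "", tr[[4]]),
    chrom = normalize_chrom(tr[[1]]), start = as.numeric(tr[[2]]),
    end = as.numeric(tr[[3]]), direction = tr[[6]],
    true_mean_log2 = tr[[5]] / 1000,
    origin = sub("^.*:", "", tr[[4]]), stringsAsFactors = FALSE)
  list(profiles = profiles, metas = metas,
       catalog = read_cnv_catalog(file.path(dir, "catalog.bed")),
       truth = truth)
}
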
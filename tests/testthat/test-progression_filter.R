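one_call <- function(chrom = "chr1", start = 0, end = 1000,
                     direction = "gain", sample_id = "s1") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             mean_log2 = if (direction == "gain") 0.58 else -1,
             sd_log2 = 0.1, n_markers = 20L, direction = direction,
             linear_ratio = if (direction == "gain") 2^0.58 else 0.5,
             stringsAsFactors = FALSE)
}

test_that("population CNV filter removes only common same-direction matches", {
  call <- one_call()
  cat_common <- cnv_catalog("chr1", 0, 1000, "gain", 0.2)
  res <- filter_population_cnvs(call, cat_common, 0.5, 0.01)
  expect_equal(nrow(res$removed), 1L)
  expect_equal(nrow(res$kept), 0L)

  cat_loss <- cnv_catalog("chr1", 0, 1000, "loss", 0.2)
  expect_equal(nrow(filter_population_cnvs(call, cat_loss)$kept), 1L)

  cat_rare <- cnv_catalog("chr1", 0, 1000, "gain", 0.005)
  expect_equal(nrow(filter_population_cnvs(call, cat_rare,
                                           max_population_frequency =
                                             0.01)$kept), 1L)
})

test_that("group subtraction removes overlapping non-progressive calls", {
  prog <- rbind(one_call("chr1", 0, 1000),
                one_call("chr2", 5000, 9000),
                one_call("chr3", 0, 2000, "loss"))
  nonprog <- one_call("chr1", 100, 1100, sample_id = "np1")
  res <- subtract_group_cnas(prog, nonprog)
  expect_equal(nrow(res$kept), 2L)
  expect_equal(res$removed$chrom, "chr1")

  all_kept <- subtract_group_cnas(prog, prog[0, ])
  expect_equal(nrow(all_kept$kept), 3L)
})

test_that("subtraction agrees with the quadratic all-pairs oracle", {
  set.seed(31)
  for (rep in 1:3) {
    prog <- random_calls(200)
    nonprog <- random_calls(80)
    res <- subtract_group_cnas(prog, nonprog, 0.5)
    removed <- oracle_subtract_removed(prog, nonprog, 0.5)
    expect_equal(nrow(res$removed), sum(removed))
    expect_equal(nrow(res$kept), sum(!removed))
    # conservation: kept and removed partition the input
    expect_equal(nrow(res$kept) + nrow(res$removed), nrow(prog))
    recon <- rbind(res$kept, res$removed)
    recon <- recon[order(recon$chrom, recon$start, recon$sample_id), ]
    orig <- prog[order(prog$chrom, prog$start, prog$sample_id), ]
    rownames(recon) <- rownames(orig) <- NULL
    expect_equal(recon, orig)
  }
})

test_that("recurrent regions reproduce cohort frequencies", {
  # 20 of 25 progressive samples carry overlapping chr1 gains
  metas <- sample_meta(sprintf("s%02d", 1:25), sprintf("p%02d", 1:25),
                       rep("OSCC", 25), rep("carcinoma", 25), rep(1L, 25))
  calls <- do.call(rbind, lapply(1:20, function(i) {
    one_call("chr1", 1000 + 10 * i, 51000 + 10 * i,
             sample_id = sprintf("s%02d", i))
  }))
  reg <- build_recurrent_regions(calls, metas)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$frequency, 0.80)
  expect_equal(reg$n_present, 20)

  # calls on different chromosomes form separate regions
  calls2 <- rbind(one_call("chr1", 0, 1000, sample_id = "s01"),
                  one_call("chr2", 0, 1000, sample_id = "s02"))
  expect_equal(nrow(build_recurrent_regions(calls2, metas)), 2L)

  # identical intervals: minimal region equals the interval itself
  calls3 <- do.call(rbind, lapply(1:3, function(i) {
    one_call("chr1", 5000, 9000, sample_id = sprintf("s%02d", i))
  }))
  reg3 <- build_recurrent_regions(calls3, metas)
  expect_equal(c(reg3$min_start, reg3$min_end), c(5000, 9000))
})

test_that("single-linkage chains fall back to the deepest-coverage core", {
  metas <- sample_meta(c("a", "b", "c"), c("a", "b", "c"),
                       rep("OSCC", 3), rep("carcinoma", 3), rep(1L, 3))
  calls <- rbind(one_call("chr1", 0, 100, sample_id = "a"),
                 one_call("chr1", 50, 150, sample_id = "b"),
                 one_call("chr1", 100, 200, sample_id = "c"))
  reg <- build_recurrent_regions(calls, metas, 0.5,
                                 group = c("PL", "OSCC"))
  expect_equal(nrow(reg), 1L)          # chained: a-b and b-c overlap at 0.5
  expect_equal(c(reg$start, reg$end), c(0, 200))
  expect_equal(c(reg$min_start, reg$min_end), c(50, 150))
})

test_that("region clustering equals brute-force union-find components", {
  set.seed(32)
  metas <- sample_meta(sprintf("S%02d", 1:5), sprintf("S%02d", 1:5),
                       rep("OSCC", 5), rep("carcinoma", 5), rep(1L, 5))
  calls <- random_calls(150)
  reg <- build_recurrent_regions(calls, metas, 0.5)
  comp <- oracle_components(calls, 0.5)
  expect_equal(nrow(reg), length(unique(comp)))
  # per-component union spans match some region exactly
  spans <- vapply(split(seq_along(comp), comp), function(ii) {
    paste(calls$chrom[ii[1]], min(calls$start[ii]), max(calls$end[ii]),
          calls$direction[ii[1]])
  }, character(1))
  expect_setequal(paste(reg$chrom, reg$start, reg$end, reg$direction),
                  unname(spans))

  # order invariance
  perm <- sample(nrow(calls))
  reg2 <- build_recurrent_regions(calls[perm, ], metas, 0.5)
  expect_equal(reg[, c("chrom", "start", "end", "direction", "frequency")],
               reg2[, c("chrom", "start", "end", "direction", "frequency")])
})

test_that("sequential recurrence classifies by presence along the series", {
  metas <- toy_metas()
  region <- function(samples) {
    data.frame(chrom = "chr1", start = 0, end = 1000, direction = "gain",
               min_start = 0, min_end = 1000, n_present = length(samples),
               frequency = length(samples) / 3,
               samples_present = I(list(samples)), stringsAsFactors = FALSE)
  }
  regs <- rbind(region(c("L2", "T")), region("T"), region(c("L1", "L2", "T")))
  rec <- sequential_recurrence(regs, metas)
  expect_equal(rec$region_class$classification,
               c("in_OSCC_and_preceding_OPML", "other",
                 "in_all_sequential_samples"))
  expect_equal(as.numeric(rec$summary[c("other",
                                        "in_OSCC_and_preceding_OPML",
                                        "in_all_sequential_samples")]),
               c(1, 1, 1))

  # a progressive patient without an OSCC sample is skipped with a warning
  m2 <- sample_meta(c("L1", "T", "Q1"), c("P1", "P1", "P2"),
                    c("PL", "OSCC", "PL"), c("mild", "carcinoma", "mild"),
                    c(1L, 2L, 1L))
  expect_warning(sequential_recurrence(regs[1, ], m2), "skipped: P2")
})

test_that("frequency table percentages are self-consistent", {
  metas <- sample_meta(sprintf("s%02d", 1:25), sprintf("p%02d", 1:25),
                       rep("OSCC", 25), rep("carcinoma", 25), rep(1L, 25))
  regs <- data.frame(chrom = c("chr1", "chr2"), start = 0, end = 1000,
                     direction = "gain", min_start = 0, min_end = 1000,
                     n_present = c(17, 0), frequency = c(17, 0) / 25,
                     stringsAsFactors = FALSE)
  regs$samples_present <- I(list(sprintf("s%02d", 1:17), "zzz"))
  ft <- frequency_table(regs, metas)
  expect_equal(nrow(ft), 1L)                 # zero-present region omitted
  expect_equal(ft$percent, 68.0)             # 17 of 25
  expect_equal(ft$percent, 100 * ft$n_present / ft$n_group)
})

test_that("gene-less regions are excluded only when annotation is supplied", {
  regs <- data.frame(chrom = c("chr1", "chr2"), start = c(100, 100),
                     end = c(200, 200), direction = "gain",
                     min_start = 100, min_end = 200, n_present = 1,
                     frequency = 0.5, stringsAsFactors = FALSE)
  regs$samples_present <- I(list("s1", "s1"))
  genes <- data.frame(chrom = "chr1", start = 150, end = 400,
                      name = "PARP1", stringsAsFactors = FALSE)
  out <- annotate_genes(regs, genes)
  expect_equal(nrow(out), 1L)
  expect_equal(out$genes, "PARP1")
  expect_message(same <- annotate_genes(regs, NULL), "skipped")
  expect_equal(nrow(same), 2L)
})

test_that("locus lookup honours half-open boundaries", {
  regs <- data.frame(chrom = "chr1", start = 100, end = 200,
                     direction = "gain", min_start = 100, min_end = 200,
                     n_present = 1, frequency = 0.5, stringsAsFactors = FALSE)
  regs$samples_present <- I(list("s1"))
  expect_equal(nrow(locus_in_regions(genomic_interval("chr1", 150, 151),
                                     regs)), 1L)
  expect_equal(nrow(locus_in_regions(genomic_interval("chr1", 200, 201),
                                     regs)), 0L)
  expect_equal(nrow(locus_in_regions(genomic_interval("chr2", 150, 151),
                                     regs)), 0L)
})
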
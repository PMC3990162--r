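test_that("reciprocal_overlap matches its defining arithmetic", {
  expect_equal(reciprocal_overlap(genomic_interval("chr1", 100, 200),
                                  genomic_interval("chr1", 150, 250)), 0.5)
  expect_equal(reciprocal_overlap(genomic_interval("chr1", 0, 100),
                                  genomic_interval("chr1", 200, 300)), 0)
  expect_equal(reciprocal_overlap(genomic_interval("chr1", 0, 1000),
                                  genomic_interval("chr1", 0, 100)), 0.1)
  expect_equal(reciprocal_overlap(genomic_interval("chr1", 0, 100),
                                  genomic_interval("chr2", 0, 100)), 0)
})

test_that("reciprocal_overlap is symmetric and 1 on itself", {
  set.seed(5)
  for (i in 1:200) {
    a <- sort(sample.int(1e6, 2)); b <- sort(sample.int(1e6, 2))
    ia <- genomic_interval(sample(paste0("chr", 1:3), 1), a[1], a[2])
    ib <- genomic_interval(sample(paste0("chr", 1:3), 1), b[1], b[2])
    expect_identical(reciprocal_overlap(ia, ib), reciprocal_overlap(ib, ia))
    expect_equal(reciprocal_overlap(ia, ia), 1)
  }
})

test_that("genomic_interval validates its invariants", {
  expect_error(genomic_interval("chrX", 0, 10), "autosome")
  expect_error(genomic_interval("chr1", 10, 10), "start < end")
  expect_equal(genomic_interval("3", 0, 10)$chrom, "chr3")
})

test_that("probe reader drops sex chromosomes, sorts, and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tposition\tlog2_ratio",
               "chr1\t100\t0.0", "chr1\t200\t0.1", "chrX\t50\t2.0"), f)
  expect_message(p <- read_probe_profile(f, "s1"), "dropped 1")
  expect_equal(nrow(p), 2L)
  expect_equal(p$pos, c(100, 200))

  # unsorted file reads the same as the sorted one
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tposition\tlog2_ratio",
               "chr2\t50\t0.3", "chr1\t200\t0.1", "chr1\t100\t0.0"), f2)
  p2 <- read_probe_profile(f2, "s1")
  expect_equal(p2$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(p2$log2_ratio, c(0.0, 0.1, 0.3))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tposition\tlog2_ratio",
               "chr1\t100\t0.0", "chr1\tnot_a_number\t0.1"), f3)
  expect_error(read_probe_profile(f3), "line 3")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tposition\tlog2_ratio", "chrX\t50\t2.0"), f4)
  expect_error(suppressMessages(read_probe_profile(f4)), "no autosomal")
})

test_that("probe profile round-trips through the TSV writer", {
  set.seed(2)
  n <- 10000L
  prof <- probe_profile(rep(paste0("chr", 1:4), each = n / 4),
                        rep((1:(n / 4)) * 7000, 4),
                        rnorm(n, 0, 0.2), sample_id = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_profile(prof, f)
  back <- read_probe_profile(f, "rt")
  expect_equal(back$chrom, prof$chrom)
  expect_equal(back$pos, prof$pos)
  expect_equal(back$log2_ratio, prof$log2_ratio)
})

test_that("call BED writer emits the documented format and round-trips", {
  calls <- data.frame(sample_id = "s1", chrom = "chr1", start = 1000,
                      end = 5000, mean_log2 = 0.3, sd_log2 = 0.05,
                      n_markers = 12L, direction = "gain",
                      linear_ratio = 2^0.3, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_calls_bed(calls, f)
  expect_equal(readLines(f), "chr1\t1000\t5000\ts1:gain\t300\tgain\t12\t0.05")

  write_calls_bed(calls[0, ], f)
  expect_equal(length(readLines(f)), 0L)
  expect_equal(nrow(read_calls_bed(f)), 0L)

  set.seed(9)
  many <- random_calls(60)
  many$mean_log2 <- round(rnorm(60, 0, 0.4), 3)   # 3-decimal score contract
  write_calls_bed(many, f)
  back <- read_calls_bed(f)
  for (col in c("sample_id", "chrom", "start", "end", "n_markers",
                "direction")) {
    expect_identical(back[[col]], many[[col]])
  }
  expect_equal(back$mean_log2, many$mean_log2, tolerance = 1e-12)
})

test_that("sample sheet parsing assigns mixed grades to the higher grade", {
  expect_equal(parse_grade("Severe dysplasia + carcinoma in situ"),
               "severe_or_CIS")
  expect_equal(parse_grade("Moderate + Severe dysplasia"), "severe_or_CIS")
  expect_equal(parse_grade("Mild squamous hyperplasia"), "non_dysplastic")
  expect_equal(parse_grade("Invasive moderately differentiated OSCC"),
               "carcinoma")
  expect_error(parse_grade("frank gibberish"), "unrecognized")
})

test_that("sample sheet reader validates and round-trips", {
  m <- toy_metas()
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(m, f)
  back <- read_sample_sheet(f)
  expect_equal(as.data.frame(back), as.data.frame(m))

  expect_error(sample_meta(c("a", "a"), c("p", "p"), c("PL", "PL"),
                           c("mild", "mild"), 1:2), "duplicate sample_id")
  expect_error(sample_meta("a", "p", "OSCC", "mild", 1L),
               "non-carcinoma")
  expect_error(sample_meta(c("a", "b"), c("p", "p"), c("PL", "PL"),
                           c("mild", "mild"), c(1L, 1L)),
               "lesion_order")
})

test_that("bundled synthetic sample sheet parses cleanly", {
  f <- system.file("extdata", "sample_sheet_synthetic.csv",
                   package = "cnaprog")
  m <- read_sample_sheet(f)
  expect_equal(nrow(m), 29L)
  expect_equal(m$grade[m$sample_id == "10e"], "severe_or_CIS")
  expect_equal(m$grade[m$sample_id == "10d"], "severe_or_CIS")
  expect_equal(m$grade[m$sample_id == "1b"], "non_dysplastic")
  expect_equal(m$grade[m$sample_id == "4d"], "carcinoma")
  expect_true(all(m$grade[m$group == "OSCC"] == "carcinoma"))
  # five progressive series each ending in a carcinoma
  prog <- m[m$group %in% c("PL", "OSCC"), ]
  expect_equal(length(unique(prog$patient_id)), 5L)
})

test_that("CNV catalog reader defaults missing frequency to 1", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\tgain", "chr2\t500\t2500\tloss"), f)
  cat4 <- read_cnv_catalog(f)
  expect_equal(cat4$frequency, c(1, 1))
  writeLines("chr1\t0\t1000\tgain\t0.12", f)
  expect_equal(read_cnv_catalog(f)$frequency, 0.12)
})

test_that("cytoband annotation decorates intervals with band labels", {
  cb <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                   band = c("p36.1", "p35"))
  x <- data.frame(chrom = "chr1", start = 5e5, end = 6e5)
  expect_equal(annotate_bands(x, cb)$band, "1p36.1")
  x2 <- data.frame(chrom = "chr1", start = 5e5, end = 1.5e6)
  expect_equal(annotate_bands(x2, cb)$band, "1p36.1-1p35")
})
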
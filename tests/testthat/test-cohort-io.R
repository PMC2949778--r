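loci <- canonical_loci()

test_that("genotype one-hot coding places the single 1 at the class index", {
  expect_identical(encode_genotype("AA", loci$MTRR66), c(1L, 0L, 0L))
  expect_identical(encode_genotype("AG", loci$MTRR66), c(0L, 1L, 0L))
  expect_identical(encode_genotype("GG", loci$MTRR66), c(0L, 0L, 1L))
  expect_error(encode_genotype("ZZ", loci$MTRR66), "MTRR66.*ZZ")
})

test_that("encoded cohorts have 22 bounded columns with per-locus indicator sums of 1", {
  cfg <- calibrate_from_summary(reference_summary())
  for (seed in 1:3) {
    em <- encode_cohort(generate_cohort(cfg, seed = seed))
    expect_equal(ncol(em$X), 22L)
    expect_true(all(em$X >= 0 & em$X <= 1))
    for (nm in names(loci)) {
      block <- em$X[, paste(nm, loci[[nm]]$labels, sep = "_")]
      expect_equal(unname(rowSums(block)), rep(1, nrow(em$X)))
    }
    # min-max endpoints of the BNMN column
    expect_equal(max(em$X[, "BNMN"]), 1)
    expect_equal(min(em$X[, "BNMN"]), 0)
    expect_identical(em$y, as.integer(generate_cohort(cfg, seed = seed)$group == "MDS"))
  }
})

test_that("write/read round trip is the identity on valid cohorts", {
  cfg <- calibrate_from_summary(reference_summary())
  for (seed in 4:5) {
    ds <- generate_cohort(cfg, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(ds, path)
    back <- read_cohort(path)
    expect_equal(as.data.frame(back), as.data.frame(ds))
    expect_identical(names(cohort_loci <- attr(back, "loci")), names(loci))
  }
})

test_that("CSV ingestion accepts decimal commas and reports bad rows by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- c("subject_id", "group", "bnmn", names(loci))
  row1 <- c("s1", "MDS", "\"16,5\"", "CC", "AA", "AA", "AA", "GG", "2R/2R", "+/+")
  row2 <- c("s2", "control", "9.3", "CT", "AC", "AG", "AG", "GA", "2R/3R", "+/-")
  writeLines(c(paste(hdr, collapse = ","), paste(row1, collapse = ","),
               paste(row2, collapse = ",")), path)
  ds <- read_cohort(path)
  expect_equal(ds$bnmn, c(16.5, 9.3))

  # unknown genotype label is rejected with its row number
  bad <- sub("CT", "XX", readLines(path))
  writeLines(bad, path)
  expect_error(read_cohort(path), "MTHFR677.*XX.*2")

  # unparseable BNMN is rejected with its line
  writeLines(c(paste(hdr, collapse = ","),
               paste(sub("\"16,5\"", "abc", row1), collapse = ",")), path)
  expect_error(read_cohort(path), "unparseable BNMN.*1")

  # missing column
  writeLines(c(paste(hdr[-3], collapse = ","),
               paste(row1[-3], collapse = ",")), path)
  expect_error(read_cohort(path), "missing column 'bnmn'")
})

test_that("column-name mapping absorbs alternative header spellings", {
  ds <- table1_reference_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(ds)
  names(df)[names(df) == "bnmn"] <- "BNMN permille"
  names(df)[names(df) == "group"] <- "status"
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_cohort(path, col_map = c(bnmn = "BNMN permille", group = "status"))
  expect_equal(back$bnmn, ds$bnmn, tolerance = 1e-12)
  expect_identical(back$group, ds$group)
})

test_that("cohort summary reproduces the published per-group distribution", {
  ds <- table1_reference_cohort()
  gs <- summarize_cohort(ds)
  expect_identical(unname(gs$counts$MTHFR677["MDS", ]), c(5L, 19L, 5L))
  expect_identical(unname(gs$counts$RFC1_80["control", ]), c(10L, 12L, 10L))
  expect_identical(unname(gs$counts$MTHFR1298[, "CC"]), c(0L, 0L))
  expect_equal(unname(gs$bnmn_mean), c(16.5, 9.3))
  expect_equal(unname(gs$bnmn_sd), c(7.6, 3.1))
  # counts always sum to the group n, also on random cohorts
  cfg <- calibrate_from_summary(reference_summary())
  gs2 <- summarize_cohort(generate_cohort(cfg, seed = 9))
  for (nm in names(gs2$counts))
    expect_equal(unname(rowSums(gs2$counts[[nm]])), unname(as.numeric(gs2$n)))
})

test_that("a single-record group reports SD 0 with a flag", {
  df <- as.data.frame(table1_reference_cohort())
  df <- df[c(1, which(df$group == "control")), ]
  gs <- summarize_cohort(cohort(df))
  expect_identical(gs$bnmn_sd[["MDS"]], 0)
  expect_true(gs$bnmn_sd_flag[["MDS"]])
  expect_false(gs$bnmn_sd_flag[["control"]])
})

test_that("summarize and analysis operations require both groups", {
  df <- as.data.frame(table1_reference_cohort())
  expect_error(summarize_cohort(cohort(df[df$group == "MDS", ])),
               "non-empty")
})

test_that("correlation screen matches brute-force Pearson and flags zero variance", {
  # tiny hand-checkable case
  em <- structure(list(X = cbind(x = c(2, 4, 1, 3) / 4), y = c(1L, 1L, 0L, 0L),
                       feature_names = "x", bnmn_scaling = c(0, 1),
                       subject_ids = letters[1:4]), class = "encoded_matrix")
  expect_equal(correlation_screen(em)$r, 0.4472136, tolerance = 1e-6)

  # random 50 x 22 matrices against the naive implementation
  withr::with_seed(42, {
    X <- matrix(runif(50 * 22), 50, dimnames = list(NULL, paste0("f", 1:22)))
    y <- rep(c(0L, 1L), 25)
    em <- structure(list(X = X, y = y, feature_names = colnames(X),
                         bnmn_scaling = c(0, 1),
                         subject_ids = as.character(1:50)),
                    class = "encoded_matrix")
    sc <- correlation_screen(em)
    for (j in seq_len(ncol(X))) {
      expect_equal(sc$r[sc$feature == colnames(X)[j]],
                   brute_pearson(X[, j], y), tolerance = 1e-12)
    }
    expect_identical(sc$r, sc$r[order(-abs(sc$r))])
  })

  # constant feature -> r = 0, flagged
  em$X[, 3] <- 0.5
  sc <- correlation_screen(em)
  expect_identical(sc$r[sc$feature == "f3"], 0)
  expect_true(sc$zero_variance[sc$feature == "f3"])
})

test_that("a balanced feature with identical group distributions has r = 0", {
  X <- cbind(f = rep(c(0, 1), 10))
  y <- rep(c(0L, 0L, 1L, 1L), 5)[order(rep(c(0, 1), 10))]
  # arrange x identically across both classes
  x <- rep(c(0, 1), each = 10)
  y <- rep(c(0L, 1L), 10)
  em <- structure(list(X = cbind(f = x), y = y, feature_names = "f",
                       bnmn_scaling = c(0, 1),
                       subject_ids = as.character(1:20)),
                  class = "encoded_matrix")
  expect_equal(correlation_screen(em)$r, 0, tolerance = 1e-12)
})
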
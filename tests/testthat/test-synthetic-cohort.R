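test_that("calibration turns counts into frequencies and validates them", {
  cfg <- calibrate_from_summary(reference_summary())
  expect_equal(cfg$genotype_probs$MDS$MTHFR677[3], 5 / 29)
  expect_equal(cfg$genotype_probs$MDS$MTHFR1298[3], 0)
  expect_equal(cfg$genotype_probs$control$MTHFR1298[3], 0)
  expect_equal(cfg$bnmn_params$MDS, c(16.5, 7.6))
  expect_equal(cfg$n_mds + cfg$n_ctrl, 61L)

  tampered <- reference_summary()
  tampered$counts$MTHFR677["MDS", "TT"] <- 6L  # 5+19+6 = 30 != 29
  expect_error(calibrate_from_summary(tampered), "sum to 30")
})

test_that("generation is deterministic and respects group sizes", {
  cfg <- calibrate_from_summary(reference_summary())
  d1 <- generate_cohort(cfg, seed = 2)
  d2 <- generate_cohort(cfg, seed = 2)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(unname(table(d1$group)["MDS"]), 29L)
  expect_identical(unname(table(d1$group)["control"]), 32L)
  d3 <- generate_cohort(cfg, seed = 3)
  expect_false(identical(d1$bnmn, d3$bnmn))
})

test_that("large-sample genotype marginals recover the calibrated frequencies", {
  gs <- reference_summary()
  cfg <- calibrate_from_summary(gs)
  cfg$n_mds <- 10000L; cfg$n_ctrl <- 10000L
  ds <- generate_cohort(cfg, seed = 4)
  emp <- summarize_cohort(ds)
  for (g in c("MDS", "control")) {
    for (nm in names(gs$counts)) {
      p <- gs$counts[[nm]][g, ] / sum(gs$counts[[nm]][g, ])
      phat <- emp$counts[[nm]][g, ] / 10000
      se <- sqrt(p * (1 - p) / 10000)
      expect_true(all(abs(phat - p) <= 4 * se + 1e-12),
                  label = paste("marginals for", g, nm))
    }
  }
})

test_that("large-sample BNMN moments recover the configured parameters", {
  cfg <- calibrate_from_summary(reference_summary())
  cfg$n_mds <- 10000L; cfg$n_ctrl <- 10000L
  ds <- generate_cohort(cfg, seed = 5)
  for (g in c("MDS", "control")) {
    x <- ds$bnmn[ds$group == g]
    mu <- cfg$bnmn_params[[g]][1]; sg <- cfg$bnmn_params[[g]][2]
    expect_true(all(x >= 0))
    # 3 Monte-Carlo SEs, with room for the (tiny) truncation shift
    expect_lt(abs(mean(x) - mu), 3 * sg / sqrt(10000) + 0.02 * sg)
    expect_lt(abs(sd(x) - sg), 3 * sg / sqrt(2 * 10000) + 0.02 * sg)
  }
})

test_that("a zero-frequency haplotype forbids the corresponding genotype pairs", {
  base <- calibrate_from_summary(reference_summary())
  cfg <- plant_haplotype_coupling(base, "MTHFR677", "MTHFR1298", c("T", "C"), 0)
  cfg <- plant_haplotype_coupling(cfg, "TYMS_28bp", "TYMS_6bp", c("2R", "-"), 0)
  for (seed in 1:3) {
    ds <- generate_cohort(cfg, seed = seed)
    # 677TT requires two T haplotypes, each forced to carry 1298A
    expect_false(any(ds$MTHFR677 == "TT" & ds$MTHFR1298 %in% c("AC", "CC")))
    # no chromosome carries both 2R and the 6bp deletion
    expect_false(any(ds$TYMS_28bp == "2R/2R" & ds$TYMS_6bp == "-/-"))
  }
})

test_that("haplotype couplings preserve allele marginals and reject infeasible requests", {
  base <- calibrate_from_summary(reference_summary())
  cfg <- plant_haplotype_coupling(base, "MTHFR677", "MTHFR1298", c("T", "C"), 0)
  cp <- cfg$couplings[[1]]
  for (g in c("MDS", "control")) {
    hm <- cp$haps[[g]]
    expect_equal(sum(hm), 1, tolerance = 1e-12)
    expect_true(all(hm >= 0))
    # row/col sums = allele frequencies implied by the genotype probabilities
    p677 <- base$genotype_probs[[g]]$MTHFR677
    p1298 <- base$genotype_probs[[g]]$MTHFR1298
    expect_equal(unname(rowSums(hm)["T"]), p677[3] + p677[2] / 2,
                 tolerance = 1e-12)
    expect_equal(unname(colSums(hm)["C"]), p1298[3] + p1298[2] / 2,
                 tolerance = 1e-12)
    # implied 3x3 genotype-pair distribution under random haplotype union
    # has no negative mass and sums to 1
    cells <- as.vector(hm)
    aa <- c(rownames(hm)[c(1, 2, 1, 2)])
    bb <- c(colnames(hm)[c(1, 1, 2, 2)])
    probs <- matrix(0, 3, 3)
    for (h1 in 1:4) for (h2 in 1:4) {
      ga <- (aa[h1] == "T") + (aa[h2] == "T")
      gb <- (bb[h1] == "C") + (bb[h2] == "C")
      probs[ga + 1, gb + 1] <- probs[ga + 1, gb + 1] + cells[h1] * cells[h2]
    }
    expect_true(all(probs >= 0))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
  # a rare-haplotype frequency larger than an allele marginal is impossible
  expect_error(
    plant_haplotype_coupling(base, "MTHFR677", "MTHFR1298", c("T", "C"), 0.9),
    "infeasible")
  expect_error(
    plant_haplotype_coupling(cfg, "MTHFR677", "MTRR66", c("T", "G"), 0),
    "at most one coupling")
})

test_that("independence-frequency coupling leaves the locus pair unassociated", {
  base <- calibrate_from_summary(reference_summary())
  cfg <- plant_haplotype_coupling(base, "MTHFR677", "MTHFR1298",
                                  c("T", "C"), "independence")
  cfg$n_mds <- 400L; cfg$n_ctrl <- 1L
  reject <- 0L
  withr::with_seed(17, {
    for (rep in 1:60) {
      ds <- generate_cohort(cfg, seed = sample.int(1e6, 1))
      sub <- as.data.frame(ds)[ds$group == "MDS", ]
      tab <- table(sub$MTHFR677, sub$MTHFR1298)
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      if (!is.na(p) && p < 0.05) reject <- reject + 1L
    }
  })
  # 60 tests at level 0.05: expect ~3 rejections, bound generous
  expect_lte(reject, 10L)
})

test_that("noise loci are group-independent padding", {
  base <- calibrate_from_summary(reference_summary())
  expect_identical(append_noise_loci(base, 0), base)
  cfg <- append_noise_loci(base, 15, seed = 8)
  expect_length(cfg$loci, 22L)
  em <- encode_cohort(generate_cohort(cfg, seed = 6))
  expect_equal(ncol(em$X), 22L + 45L)
  for (nm in grep("^NOISE", names(cfg$loci), value = TRUE))
    expect_identical(cfg$genotype_probs$MDS[[nm]],
                     cfg$genotype_probs$control[[nm]])
  # probabilities are drawn once: same seed, same padding
  expect_identical(append_noise_loci(base, 15, seed = 8)$genotype_probs,
                   cfg$genotype_probs)
})

test_that("noise-locus indicators are uncorrelated with case status at large n", {
  base <- calibrate_from_summary(reference_summary())
  cfg <- append_noise_loci(base, 2, seed = 12)
  cfg$n_mds <- 2500L; cfg$n_ctrl <- 2500L
  small <- 0L; total <- 0L
  for (seed in 1:20) {
    em <- encode_cohort(generate_cohort(cfg, seed = seed))
    r <- correlation_screen(em)
    rn <- r$r[grepl("^NOISE", r$feature)]
    small <- small + sum(abs(rn) < 0.05)
    total <- total + length(rn)
  }
  expect_gte(small / total, 0.95)
})
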
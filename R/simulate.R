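#' Generator configuration for synthetic cohorts
#'
#' Holds everything [generate_cohort()] needs: group sizes, per-(group, locus)
#' genotype-class probabilities, per-group BNMN normal parameters (the normal
#' is truncated at 0 when sampling), haplotype couplings for linked locus
#' pairs, and a seed.
#'
#' @param n_mds,n_ctrl Group sizes (>= 1).
#' @param genotype_probs List `group -> locus -> probability triple` (each
#'   triple sums to 1).
#' @param bnmn_params List `group -> c(mean, sd)` in per-mille; sd > 0.
#' @param loci Named list of [locus_schema()] objects.
#' @param couplings List of haplotype couplings (see
#'   [plant_haplotype_coupling()]).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `generator_config`.
#' @export
generator_config <- function(n_mds, n_ctrl, genotype_probs, bnmn_params,
                             loci = canonical_loci(), couplings = list(),
                             seed = 1L) {
  cfg <- structure(list(n_mds = as.integer(n_mds), n_ctrl = as.integer(n_ctrl),
                        loci = loci, genotype_probs = genotype_probs,
                        bnmn_params = bnmn_params, couplings = couplings,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_mds >= 1L, cfg$n_ctrl >= 1L)
  for (g in c("MDS", "control")) {
    for (nm in names(cfg$loci)) {
      p <- cfg$genotype_probs[[g]][[nm]]
      if (is.null(p) || length(p) != 3L)
        stop("missing genotype probabilities for (", g, ", ", nm, ")")
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("genotype probabilities for (", g, ", ", nm,
             ") must be nonnegative and sum to 1")
    }
    bp <- cfg$bnmn_params[[g]]
    if (is.null(bp) || length(bp) != 2L || bp[2] <= 0)
      stop("bnmn_params[['", g, "']] must be c(mean, sd) with sd > 0")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> n =", x$n_mds, "MDS +", x$n_ctrl, "control;",
      length(x$loci), "loci;", length(x$couplings), "coupling(s); seed",
      x$seed, "\n")
  invisible(x)
}

#' Calibrate a generator from a cohort summary
#'
#' Genotype probabilities become `count / n` per group and locus; BNMN
#' parameters are taken from the summary's per-group mean and SD. No
#' couplings are added here (see [plant_haplotype_coupling()]).
#'
#' @param gs A `cohort_summary`, e.g. [reference_summary()] or the output of
#'   [summarize_cohort()].
#' @param seed Default generation seed stored in the config.
#' @return A [generator_config()].
#' @export
calibrate_from_summary <- function(gs, seed = 1L) {
  groups <- c("MDS", "control")
  for (nm in names(gs$counts)) {
    sums <- rowSums(gs$counts[[nm]])
    bad <- sums != gs$n[groups]
    if (any(bad))
      stop("locus '", nm, "': genotype counts sum to ",
           paste(sums[bad], collapse = ", "), " but group n is ",
           paste(gs$n[groups][bad], collapse = ", "))
  }
  probs <- lapply(setNames(groups, groups), function(g) {
    lapply(gs$counts, function(m) unname(m[g, ] / sum(m[g, ])))
  })
  bnmn <- lapply(setNames(groups, groups), function(g)
    c(gs$bnmn_mean[[g]], gs$bnmn_sd[[g]]))
  generator_config(gs$n[["MDS"]], gs$n[["control"]], probs, bnmn,
                   loci = gs$loci, seed = seed)
}

# Frequency of a named allele implied by a locus's genotype probabilities
# (heterozygotes carry one copy of each allele).
allele_freq <- function(probs, allele, schema) {
  i <- match(allele, schema$alleles)
  if (is.na(i)) stop("locus '", schema$name, "': unknown allele '", allele, "'")
  if (i == 1L) probs[1] + probs[2] / 2 else probs[3] + probs[2] / 2
}

#' Plant a haplotype coupling between two loci
#'
#' Couples two biallelic loci so that their genotypes are generated from
#' pairs of two-locus haplotypes (random union of two haplotypes per
#' subject). The named haplotype is set to frequency `freq` (default 0: the
#' haplotype never occurs, the strongest possible linkage disequilibrium);
#' the other three haplotype frequencies are solved so that the single-locus
#' allele frequencies implied by the genotype probabilities are preserved.
#' Typical uses are the rare 677T-1298C MTHFR haplotype and the rare
#' 2R-deletion TYMS haplotype.
#'
#' @param cfg A [generator_config()].
#' @param locus_a,locus_b Names of the two loci (must be distinct and not
#'   already coupled).
#' @param rare_haplotype `c(allele_at_a, allele_at_b)` naming the haplotype.
#' @param freq Its frequency (applied in both groups), or `"independence"`
#'   for the product of the two allele frequencies (no linkage).
#' @return The updated config.
#' @export
plant_haplotype_coupling <- function(cfg, locus_a, locus_b,
                                     rare_haplotype, freq = 0) {
  validate_generator_config(cfg)
  if (locus_a == locus_b) stop("loci must be distinct")
  sa <- cfg$loci[[locus_a]]; sb <- cfg$loci[[locus_b]]
  if (is.null(sa) || is.null(sb)) stop("unknown locus name")
  taken <- unlist(lapply(cfg$couplings, function(cp) c(cp$locus_a, cp$locus_b)))
  if (any(c(locus_a, locus_b) %in% taken))
    stop("a locus can take part in at most one coupling")
  haps <- lapply(setNames(c("MDS", "control"), c("MDS", "control")), function(g) {
    u <- allele_freq(cfg$genotype_probs[[g]][[locus_a]], rare_haplotype[1], sa)
    v <- allele_freq(cfg$genotype_probs[[g]][[locus_b]], rare_haplotype[2], sb)
    f <- if (identical(freq, "independence")) u * v else as.numeric(freq)
    cells <- c(f, u - f, v - f, 1 - u - v + f)
    names(cells) <- c("rare", "a_only", "b_only", "neither")
    bad <- cells < -1e-12
    if (any(bad))
      stop("infeasible coupling in group ", g, ": haplotype frequency '",
           names(cells)[which(bad)[1]], "' = ",
           signif(cells[which(bad)[1]], 4),
           " (rare-haplotype frequency exceeds an allele marginal)")
    cells <- pmax(cells, 0)
    # 2 x 2 matrix indexed by (allele at a) x (allele at b); row/col 1 is the
    # rare haplotype's allele at that locus (column-major: [2,1] carries only
    # b's rare allele, [1,2] only a's).
    m <- matrix(c(cells["rare"], cells["b_only"], cells["a_only"],
                  cells["neither"]), 2, 2,
                dimnames = list(
                  c(rare_haplotype[1],
                    setdiff(sa$alleles, rare_haplotype[1])),
                  c(rare_haplotype[2],
                    setdiff(sb$alleles, rare_haplotype[2]))))
    m
  })
  cfg$couplings <- c(cfg$couplings,
                     list(list(locus_a = locus_a, locus_b = locus_b,
                               haps = haps)))
  cfg
}

#' Append uninformative noise loci
#'
#' Adds `k` extra loci whose genotype probabilities are identical in both
#' groups (drawn once under `seed` from Hardy-Weinberg proportions with a
#' uniform allele frequency, then fixed), so they carry no association with
#' case status by construction. Useful for feature-selection recovery
#' experiments.
#'
#' @param cfg A [generator_config()].
#' @param k Number of noise loci (>= 0).
#' @param seed Seed for the one-off probability draw.
#' @return The updated config.
#' @export
append_noise_loci <- function(cfg, k, seed = 100L) {
  stopifnot(k >= 0)
  if (k == 0) return(cfg)
  existing <- sum(grepl("^NOISE", names(cfg$loci)))
  with_rng(seed, {
    for (i in seq_len(k)) {
      nm <- sprintf("NOISE%02d", existing + i)
      q <- runif(1, 0.15, 0.85)
      p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      cfg$loci[[nm]] <- locus_schema(nm, c("AA", "AB", "BB"), c("A", "B"))
      cfg$genotype_probs[["MDS"]][[nm]] <- p
      cfg$genotype_probs[["control"]][[nm]] <- p
    }
  })
  validate_generator_config(cfg)
  cfg
}

# Map per-subject counts of a schema's minor allele (row 2 of the haplotype
# matrix is the non-rare allele, so count occurrences of schema allele 2).
genotype_label_from_alleles <- function(a1, a2, schema) {
  k <- (a1 == schema$alleles[2]) + (a2 == schema$alleles[2])
  schema$labels[k + 1L]
}

#' Generate a synthetic cohort
#'
#' Uncoupled loci are drawn multinomially from the per-(group, locus)
#' genotype probabilities; coupled pairs are drawn as two two-locus
#' haplotypes per subject (random union) and collapsed to genotypes; BNMN is
#' drawn from a normal truncated at 0 with the group parameters. The same
#' (config, seed) always yields the identical dataset.
#'
#' @param cfg A [generator_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A [cohort()] of `n_mds + n_ctrl` records (MDS first).
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  validate_generator_config(cfg)
  coupled <- unlist(lapply(cfg$couplings, function(cp) c(cp$locus_a, cp$locus_b)))
  with_rng(seed, {
    grp_frames <- lapply(list(c("MDS", cfg$n_mds), c("control", cfg$n_ctrl)),
                         function(gi) {
      g <- gi[1]; n <- as.integer(gi[2])
      df <- data.frame(
        subject_id = sprintf("%s%03d", if (g == "MDS") "MDS" else "CTRL",
                             seq_len(n)),
        group = g, stringsAsFactors = FALSE)
      df$bnmn <- rnorm_trunc0(n, cfg$bnmn_params[[g]][1], cfg$bnmn_params[[g]][2])
      for (cp in cfg$couplings) {
        hm <- cp$haps[[g]]
        cells <- as.vector(hm)  # column-major over (a-allele, b-allele)
        a_alleles <- rownames(hm)[c(1, 2, 1, 2)]
        b_alleles <- colnames(hm)[c(1, 1, 2, 2)]
        h1 <- sample.int(4L, n, replace = TRUE, prob = cells)
        h2 <- sample.int(4L, n, replace = TRUE, prob = cells)
        df[[cp$locus_a]] <- genotype_label_from_alleles(
          a_alleles[h1], a_alleles[h2], cfg$loci[[cp$locus_a]])
        df[[cp$locus_b]] <- genotype_label_from_alleles(
          b_alleles[h1], b_alleles[h2], cfg$loci[[cp$locus_b]])
      }
      for (nm in setdiff(names(cfg$loci), coupled)) {
        sc <- cfg$loci[[nm]]
        df[[nm]] <- sample(sc$labels, n, replace = TRUE,
                           prob = cfg$genotype_probs[[g]][[nm]])
      }
      df
    })
    df <- rbind(grp_frames[[1]][, c("subject_id", "group", "bnmn",
                                    names(cfg$loci))],
                grp_frames[[2]][, c("subject_id", "group", "bnmn",
                                    names(cfg$loci))])
    cohort(df, cfg$loci)
  })
}

# Normal truncated at 0 by rejection; the stated (mean, sd) are the
# pre-truncation parameters.
rnorm_trunc0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- rnorm(sum(neg), mean, sd)
  x
}

#' Deterministic cohort matching the published distribution exactly
#'
#' Builds a 61-subject cohort whose per-group genotype-class counts equal the
#' published counts exactly at every locus (labels are assigned by a seeded
#' permutation, independently per locus, so loci are unassociated with each
#' other) and whose per-group BNMN values realize the published mean and
#' sample SD exactly (an equally spaced grid standardized and rescaled).
#' Useful as a summary-faithful fixture and for recomputing the univariate
#' BNMN/case-status correlation.
#'
#' @param seed Seed for the per-locus label permutations.
#' @return A [cohort()] with 29 MDS and 32 control records.
#' @export
table1_reference_cohort <- function(seed = 1L) {
  gs <- reference_summary()
  groups <- c("MDS", "control")
  with_rng(seed, {
    frames <- lapply(groups, function(g) {
      n <- gs$n[[g]]
      z <- as.numeric(scale(seq_len(n)))  # mean 0, sample SD 1 exactly
      df <- data.frame(
        subject_id = sprintf("%s%03d", if (g == "MDS") "MDS" else "CTRL",
                             seq_len(n)),
        group = g,
        bnmn = gs$bnmn_mean[[g]] + gs$bnmn_sd[[g]] * z,
        stringsAsFactors = FALSE)
      for (nm in names(gs$counts)) {
        labels <- rep(colnames(gs$counts[[nm]]), gs$counts[[nm]][g, ])
        df[[nm]] <- sample(labels)
      }
      df
    })
    cohort(rbind(frames[[1]], frames[[2]]), gs$loci)
  })
}

#' Write a synthetic cohort and its generator configuration to disk
#'
#' Writes the cohort CSV (same schema [read_cohort()] ingests) plus, when
#' requested, a JSON echo of the generator configuration.
#'
#' @param cfg A [generator_config()].
#' @param path Output CSV path.
#' @param config_path Optional JSON path for the config echo.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return The generated [cohort()], invisibly.
#' @export
generate_cohort_file <- function(cfg, path, config_path = NULL,
                                 seed = cfg$seed) {
  ds <- generate_cohort(cfg, seed = seed)
  write_cohort(ds, path)
  if (!is.null(config_path)) {
    echo <- list(
      n_mds = cfg$n_mds, n_ctrl = cfg$n_ctrl, seed = seed,
      bnmn_params = cfg$bnmn_params,
      genotype_probs = cfg$genotype_probs,
      couplings = lapply(cfg$couplings, function(cp)
        list(locus_a = cp$locus_a, locus_b = cp$locus_b,
             haplotype_freqs = lapply(cp$haps, function(m)
               as.list(setNames(as.vector(m),
                                paste(rownames(m)[c(1, 2, 1, 2)],
                                      colnames(m)[c(1, 1, 2, 2)],
                                      sep = "-")))))))
    jsonlite::write_json(echo, config_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(ds)
}
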
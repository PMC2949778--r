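#' Configuration for the TWIST evolutionary wrapper
#'
#' A genetic algorithm with tournament selection, uniform crossover, bit-flip
#' mutation, elitism and "doping" — per-generation injection of random
#' immigrant genomes replacing the worst offspring — jointly evolves a
#' train/test split and an input-variable mask scored by an inner
#' reduced-budget perceptron.
#'
#' @param population_size Genomes per generation (>= 4).
#' @param generations Number of generations.
#' @param crossover_rate Probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability; `NULL` means `1 / genome
#'   length`.
#' @param elite_count Best genomes copied unchanged (< population_size).
#' @param doping_fraction Fraction of the population replaced by random
#'   immigrants each generation.
#' @param tournament_size Tournament size for parent selection.
#' @param inner_train [train_config()] for the fitness networks (reduced
#'   budget by default; its fixed seed makes fitness a deterministic function
#'   of the genome).
#' @param seed Master seed for the evolutionary run.
#' @return A `twist_config`.
#' @export
twist_config <- function(population_size = 30L, generations = 100L,
                         crossover_rate = 0.9, mutation_rate = NULL,
                         elite_count = 2L, doping_fraction = 0.1,
                         tournament_size = 2L,
                         inner_train = train_config(max_epochs = 100L),
                         seed = 1L) {
  stopifnot(population_size >= 4L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            elite_count >= 0L, elite_count < population_size,
            doping_fraction >= 0, doping_fraction <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 doping_fraction = doping_fraction,
                 tournament_size = as.integer(tournament_size),
                 inner_train = inner_train, seed = as.integer(seed)),
            class = "twist_config")
}

#' Construct a TWIST genome
#'
#' @param split_bits Binary vector, one per record (0 = subset a, 1 = b).
#' @param mask_bits Binary vector, one per feature (1 = feature selected).
#' @return A `twist_genome`.
#' @export
twist_genome <- function(split_bits, mask_bits) {
  structure(list(split = as.integer(split_bits), mask = as.integer(mask_bits)),
            class = "twist_genome")
}

# A genome is valid when at least one feature is selected and each subset
# contains at least one member of each class.
genome_valid <- function(g, y) {
  if (sum(g$mask) < 1L) return(FALSE)
  for (s in c(0L, 1L)) {
    ys <- y[g$split == s]
    if (length(ys) == 0L || length(unique(ys)) < 2L) return(FALSE)
  }
  TRUE
}

#' Two-direction generalization fitness of a genome
#'
#' Invalid genomes (empty mask, or a subset missing a class) score 0. For
#' valid genomes an inner perceptron is trained on subset a restricted to the
#' masked features and scored on subset b, then vice versa with a fresh
#' network; the fitness is the mean of the two directions' global accuracy
#' as a proportion. Deterministic given the config (the inner networks use
#' the fixed `inner_train` seed).
#'
#' @param g A [twist_genome()].
#' @param em An [encode_cohort()] result.
#' @param cfg A [twist_config()].
#' @return Fitness in \[0, 1\].
#' @export
genome_fitness <- function(g, em, cfg = twist_config()) {
  if (!genome_valid(g, em$y)) return(0)
  cols <- which(g$mask == 1L)
  it <- cfg$inner_train
  acc <- vapply(list(c(0L, 1L), c(1L, 0L)), function(dirn) {
    tr <- g$split == dirn[1]; te <- g$split == dirn[2]
    Xtr <- em$X[tr, cols, drop = FALSE]
    ytr <- em$y[tr]
    # canonical lexicographic training order: fitness depends only on the
    # (partition, mask), not on how records happen to be ordered
    ord <- do.call(order, c(unname(as.data.frame(Xtr)), list(ytr)))
    fit <- cpp_train_mlp(Xtr[ord, , drop = FALSE], ytr[ord], 4L,
                         it$learning_rate, it$momentum, it$max_epochs,
                         isTRUE(it$shuffle), it$seed, it$early_stop_tol)
    sc <- cpp_mlp_scores(em$X[te, cols, drop = FALSE], fit$W1, fit$b1,
                         fit$W2, fit$b2)
    mean((sc >= 0.5) == (em$y[te] == 1L))
  }, numeric(1))
  mean(acc)
}

random_genome <- function(n_records, n_features) {
  twist_genome(as.integer(runif(n_records) < 0.5),
               as.integer(runif(n_features) < 0.5))
}

tournament_pick <- function(fitnesses, size) {
  idx <- sample.int(length(fitnesses), size, replace = TRUE)
  idx[which.max(fitnesses[idx])]
}

mutate_bits <- function(bits, rate) {
  flip <- runif(length(bits)) < rate
  bits[flip] <- 1L - bits[flip]
  bits
}

#' One generation of the doped genetic algorithm
#'
#' Elitism (best `elite_count` copied unchanged), tournament selection,
#' uniform crossover at `crossover_rate`, per-bit mutation, then
#' `floor(doping_fraction * population_size)` random immigrant genomes
#' replacing the offspring bred from the worst-ranked slots. Uses the
#' caller's RNG state ([evolve_twist()] seeds it once per run). The returned
#' population carries the number of injected immigrants as attribute
#' `n_doped`.
#'
#' @param population List of [twist_genome()]s.
#' @param fitnesses Numeric vector of their fitnesses.
#' @param cfg A [twist_config()].
#' @return List of genomes of the same length.
#' @export
gend_step <- function(population, fitnesses, cfg) {
  pop_n <- cfg$population_size
  stopifnot(length(population) == pop_n, length(fitnesses) == pop_n)
  n_rec <- length(population[[1]]$split)
  n_feat <- length(population[[1]]$mask)
  mut <- if (is.null(cfg$mutation_rate)) 1 / (n_rec + n_feat) else
    cfg$mutation_rate
  ord <- order(fitnesses, decreasing = TRUE)
  nxt <- vector("list", pop_n)
  for (e in seq_len(cfg$elite_count)) nxt[[e]] <- population[[ord[e]]]
  for (slot in seq(cfg$elite_count + 1L, pop_n)) {
    p1 <- population[[tournament_pick(fitnesses, cfg$tournament_size)]]
    p2 <- population[[tournament_pick(fitnesses, cfg$tournament_size)]]
    child <- if (runif(1) < cfg$crossover_rate) {
      pick_s <- runif(n_rec) < 0.5
      pick_m <- runif(n_feat) < 0.5
      twist_genome(ifelse(pick_s, p1$split, p2$split),
                   ifelse(pick_m, p1$mask, p2$mask))
    } else p1
    nxt[[slot]] <- twist_genome(mutate_bits(child$split, mut),
                                mutate_bits(child$mask, mut))
  }
  n_dope <- floor(cfg$doping_fraction * pop_n)
  if (n_dope > 0) {
    for (slot in seq(pop_n - n_dope + 1L, pop_n))
      nxt[[slot]] <- random_genome(n_rec, n_feat)
  }
  attr(nxt, "n_doped") <- as.integer(n_dope)
  nxt
}

#' Evolve a variable mask and train/test split
#'
#' Runs the doped genetic algorithm for `cfg$generations` generations over
#' genomes combining a record-split and a feature-mask, scoring each by
#' [genome_fitness()] (with per-run memoization: the fitness of a genome is
#' deterministic). Returns the best genome found, its selected features and
#' split, and the running-best fitness history. Fully reproducible given
#' `cfg$seed`.
#'
#' @param em An [encode_cohort()] result.
#' @param cfg A [twist_config()].
#' @return A `twist_result` with `selected_features`, `split` (named 'a'/'b'
#'   assignment by subject id), `best_fitness_history`, `final_fitness`,
#'   `best_genome` and `n_evaluations` (distinct genomes evaluated).
#' @export
evolve_twist <- function(em, cfg = twist_config()) {
  n_rec <- nrow(em$X); n_feat <- ncol(em$X)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(g) {
    key <- paste(c(g$split, g$mask), collapse = "")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- genome_fitness(g, em, cfg)
      cache[[key]] <- val
      n_eval <<- n_eval + 1L
    }
    val
  }
  with_rng(cfg$seed, {
    population <- replicate(cfg$population_size,
                            random_genome(n_rec, n_feat), simplify = FALSE)
    fitnesses <- vapply(population, fitness_of, numeric(1))
    best_i <- which.max(fitnesses)
    best <- population[[best_i]]; best_fit <- fitnesses[best_i]
    history <- numeric(cfg$generations)
    for (gen in seq_len(cfg$generations)) {
      population <- gend_step(population, fitnesses, cfg)
      fitnesses <- vapply(population, fitness_of, numeric(1))
      gi <- which.max(fitnesses)
      if (fitnesses[gi] > best_fit) {
        best <- population[[gi]]; best_fit <- fitnesses[gi]
      }
      history[gen] <- best_fit
    }
    structure(list(
      selected_features = em$feature_names[best$mask == 1L],
      split = setNames(ifelse(best$split == 0L, "a", "b"), em$subject_ids),
      best_fitness_history = history, final_fitness = best_fit,
      best_genome = best, n_evaluations = n_eval),
      class = "twist_result")
  })
}

#' @export
print.twist_result <- function(x, ...) {
  cat("<twist_result> final fitness ", sprintf("%.3f", x$final_fitness),
      "; ", length(x$selected_features), " variables selected:\n  ",
      paste(x$selected_features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a TWIST result as JSON
#'
#' @param tr A `twist_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_twist_result <- function(tr, path) {
  jsonlite::write_json(
    list(selected_features = tr$selected_features,
         split = as.list(tr$split),
         best_fitness_history = tr$best_fitness_history,
         final_fitness = tr$final_fitness),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
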
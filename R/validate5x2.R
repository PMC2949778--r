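#' Stratified random halving
#'
#' Splits the records into two disjoint, exhaustive halves such that each
#' class's membership differs by at most one between halves. Which half
#' receives a class's extra member alternates with the class's shuffled
#' order, but half `a` always receives the ceiling share, so 61 records
#' (29 cases / 32 controls) split as 31 / 30.
#'
#' @param em An [encode_cohort()] result (any object with a `y` vector works).
#' @param seed Seed for the within-class shuffles.
#' @return List with integer index vectors `a` and `b`.
#' @export
stratified_halves <- function(em, seed = 1L) {
  y <- em$y
  for (cls in unique(y)) {
    if (sum(y == cls) < 2L)
      stop("each class needs at least 2 members to halve")
  }
  with_rng(seed, {
    a <- integer(0); b <- integer(0)
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      k <- ceiling(length(idx) / 2)
      a <- c(a, idx[seq_len(k)])
      b <- c(b, idx[-seq_len(k)])
    }
    list(a = sort(a), b = sort(b))
  })
}

#' 5x2 cross-validation of the back-propagation perceptron
#'
#' For each of five seeds the data are randomly halved with stratification;
#' a fresh network is trained on half a and evaluated on half b, and a second
#' fresh network is trained on b and evaluated on a (weights are frozen
#' before testing; scored records never contributed to the weights that
#' score them). The ten resulting metric rows are returned together with
#' their exact arithmetic mean row.
#'
#' @param em An [encode_cohort()] result.
#' @param features Character vector (or integer indices) of the feature
#'   columns to use, typically the TWIST-selected set; must be non-empty.
#' @param train_cfg A [train_config()] for the per-run networks; each run's
#'   network is re-initialized with a run-specific seed derived from it.
#' @param seeds Five distinct integer seeds, one per halving.
#' @param hidden Hidden-layer size.
#' @return A `results_table`: data frame with 10 rows (`run`, `direction`,
#'   `sensitivity`, `specificity`, `global_accuracy`, `roc_auc`, confusion
#'   counts), with attributes `mean_row` (named numeric) and `splits` (the
#'   train/test index pairs actually used, for leakage auditing).
#' @export
run_5x2 <- function(em, features, train_cfg = train_config(),
                    seeds = 1:5, hidden = 4L) {
  if (length(features) == 0L) stop("feature subset must be non-empty")
  if (length(seeds) != 5L || anyDuplicated(seeds))
    stop("exactly 5 distinct seeds are required")
  cols <- if (is.character(features)) {
    miss <- setdiff(features, em$feature_names)
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
    match(features, em$feature_names)
  } else as.integer(features)
  rows <- list(); splits <- list()
  for (i in seq_along(seeds)) {
    halves <- stratified_halves(em, seed = seeds[i])
    for (dirn in c("a->b", "b->a")) {
      tr <- if (dirn == "a->b") halves$a else halves$b
      te <- if (dirn == "a->b") halves$b else halves$a
      # one fresh initialization per halving, shared by both directions, so
      # relabeling a<->b permutes rows without changing the mean row
      cfg_run <- train_cfg
      cfg_run$seed <- derive_seed(train_cfg$seed, "net", k = seeds[i])
      model <- train_mlp(em$X[tr, cols, drop = FALSE], em$y[tr],
                         cfg = cfg_run, hidden = hidden)
      sc <- predict_scores(model, em$X[te, cols, drop = FALSE])
      mr <- confusion_and_metrics(sc, em$y[te])
      rows[[length(rows) + 1L]] <- data.frame(
        run = i, direction = dirn, sensitivity = mr$sensitivity,
        specificity = mr$specificity, global_accuracy = mr$global_accuracy,
        roc_auc = mr$roc_auc, TP = mr$confusion[["TP"]],
        FN = mr$confusion[["FN"]], TN = mr$confusion[["TN"]],
        FP = mr$confusion[["FP"]], stringsAsFactors = FALSE)
      splits[[length(splits) + 1L]] <- list(train = tr, test = te)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- paste0("run ", out$run, ", ", out$direction)
  metric_cols <- c("sensitivity", "specificity", "global_accuracy", "roc_auc")
  mean_row <- colMeans(out[, metric_cols])
  structure(out, mean_row = mean_row, splits = splits,
            features = em$feature_names[cols],
            class = c("results_table", "data.frame"))
}

#' @export
print.results_table <- function(x, ...) {
  print.data.frame(round_df(as.data.frame(x)[, 1:6]))
  m <- attr(x, "mean_row")
  cat(sprintf("Mean    sens %.2f  spec %.2f  acc %.2f  AUC %.3f\n",
              m[["sensitivity"]], m[["specificity"]],
              m[["global_accuracy"]], m[["roc_auc"]]))
  invisible(x)
}

round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Export a 5x2 results table as TSV
#'
#' Columns follow the conventional reporting order (sensitivity,
#' specificity, global accuracy, ROC AUC); the mean row is appended last.
#'
#' @param rt A `results_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rt, path) {
  metric_cols <- c("sensitivity", "specificity", "global_accuracy", "roc_auc")
  df <- data.frame(ANN = rownames(rt), as.data.frame(rt)[, metric_cols],
                   check.names = FALSE)
  m <- attr(rt, "mean_row")
  df <- rbind(df, data.frame(ANN = "Mean", t(m[metric_cols]),
                             check.names = FALSE))
  names(df) <- c("ANN", "Sensitivity", "Specificity", "Global accuracy",
                 "ROC AUC")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
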
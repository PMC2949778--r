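#' Encode a cohort as a bounded feature matrix
#'
#' Expands every locus into its three genotype-class indicators and appends
#' the BNMN frequency min-max scaled to \[0, 1\]. The binary target is 1 for
#' MDS and 0 for control mothers. The (min, max) pair used for scaling is
#' stored so that held-out data can be encoded on the same scale.
#'
#' @param ds A [cohort()].
#' @param bnmn_scaling Optional `c(min, max)` to reuse a previously fitted
#'   BNMN scaling (values are clipped to \[0, 1\]).
#' @return An `encoded_matrix`: list with `X` (subjects x features, all
#'   entries in \[0, 1\]), `y` (binary, MDS = 1), `feature_names`,
#'   `bnmn_scaling` and `subject_ids`.
#' @export
encode_cohort <- function(ds, bnmn_scaling = NULL) {
  loci <- cohort_loci(ds)
  n <- nrow(ds)
  blocks <- lapply(loci, function(sc) {
    idx <- match(ds[[sc$name]], sc$labels)
    m <- matrix(0, n, 3L)
    m[cbind(seq_len(n), idx)] <- 1
    colnames(m) <- paste(sc$name, sc$labels, sep = "_")
    m
  })
  if (is.null(bnmn_scaling)) {
    bnmn_scaling <- c(min = min(ds$bnmn), max = max(ds$bnmn))
  }
  rng <- bnmn_scaling[2] - bnmn_scaling[1]
  if (rng <= 0) {
    warning("degenerate BNMN range; scaled BNMN column set to 0.5")
    bn <- rep(0.5, n)
  } else {
    bn <- pmin(1, pmax(0, (ds$bnmn - bnmn_scaling[1]) / rng))
  }
  X <- cbind(do.call(cbind, blocks), BNMN = bn)
  rownames(X) <- ds$subject_id
  structure(list(X = X, y = as.integer(ds$group == "MDS"),
                 feature_names = colnames(X),
                 bnmn_scaling = unname(bnmn_scaling),
                 subject_ids = ds$subject_id),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("<encoded_matrix> ", nrow(x$X), " subjects x ", ncol(x$X),
      " features (", sum(x$y), " positive)\n", sep = "")
  invisible(x)
}

#' Univariate correlation screen
#'
#' Pearson correlation of each encoded feature with the binary target (for
#' the continuous BNMN column this is the point-biserial correlation), sorted
#' by decreasing absolute value. Zero-variance features are reported with
#' r = 0 and flagged rather than dropped.
#'
#' @param em An [encode_cohort()] result; the target must contain both classes.
#' @return Data frame with columns `feature`, `r`, `zero_variance`.
#' @export
correlation_screen <- function(em) {
  if (length(unique(em$y)) < 2L) stop("target must contain both classes")
  r <- vapply(seq_len(ncol(em$X)), function(j) {
    x <- em$X[, j]
    if (sd(x) == 0) 0 else cor(x, em$y)
  }, numeric(1))
  zv <- vapply(seq_len(ncol(em$X)), function(j) sd(em$X[, j]) == 0, logical(1))
  out <- data.frame(feature = em$feature_names, r = r, zero_variance = zv,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Export an encoded matrix as TSV
#'
#' One row per subject: id, target, then every feature column, for external
#' inspection.
#'
#' @param em An [encode_cohort()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(em, path) {
  df <- data.frame(subject_id = em$subject_ids, target = em$y,
                   em$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
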
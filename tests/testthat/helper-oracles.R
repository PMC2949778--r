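# Independent brute-force oracles, kept deliberately naive.

# Pearson correlation from first principles.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# AUC by pairwise enumeration over all positive x negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Minimum spanning-tree total weight by exhaustive enumeration of all
# (n-1)-edge subsets that form a spanning tree.
brute_mst_weight <- function(D) {
  n <- nrow(D)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  best <- Inf
  for (pick in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    sub <- edges[pick, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in seq_len(nrow(sub))) {
      ri <- find(sub[e, 1]); rj <- find(sub[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(D[sub]))
  }
  best
}

# Generator config with identical marginals in both groups (no signal).
pure_noise_config <- function() {
  gs <- reference_summary()
  probs <- lapply(gs$counts, function(m) unname(m["control", ] / sum(m["control", ])))
  generator_config(29, 32,
                   list(MDS = probs, control = probs),
                   list(MDS = c(9.3, 3.1), control = c(9.3, 3.1)))
}

# Tiny encoded-matrix stand-in with one strongly informative feature and
# `k_noise` uninformative ones.
toy_encoded <- function(n = 30, k_noise = 3, seed = 1, effect = 2) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x_sig <- plogis(effect * (y - 0.5) * 2 + rnorm(n))
    X <- cbind(SIG = x_sig,
               matrix(runif(n * k_noise), n,
                      dimnames = list(NULL, paste0("N", seq_len(k_noise)))))
    structure(list(X = X, y = y, feature_names = colnames(X),
                   bnmn_scaling = c(0, 1),
                   subject_ids = sprintf("S%02d", seq_len(n))),
              class = "encoded_matrix")
  })
}
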
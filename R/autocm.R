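#' Train an Auto-Contractive Map
#'
#' The Auto-CM passes each record through two contraction stages: a
#' mono-connection weight per variable and a pairwise weight matrix. Weights
#' grow with variable co-activation and remain bounded below the contraction
#' constant `C`. Training is deterministic (zero-initialized weights, fixed
#' record order) and stops when the epoch-mean absolute weight change falls
#' below `tol` or at `max_epochs`.
#'
#' @param X01 Numeric matrix with entries in \[0, 1\], named columns
#'   recommended (one column per variable/node).
#' @param C Contraction constant; defaults to the number of variables, which
#'   guarantees the output contraction stays nonnegative.
#' @param lr Learning rate.
#' @param tol Convergence tolerance on the epoch-mean absolute weight change.
#' @param max_epochs Epoch cap.
#' @return An `autocm_model` with the mono weights `v`, the raw directed
#'   pairwise matrix `W`, its symmetrized form `Wsym` (used downstream),
#'   `C`, `epochs_run` and `converged`.
#' @export
train_autocm <- function(X01, C = ncol(X01), lr = 0.1, tol = 1e-6,
                         max_epochs = 1000L) {
  X01 <- as.matrix(X01)
  if (any(!is.finite(X01)) || any(X01 < 0) || any(X01 > 1))
    stop("Auto-CM inputs must lie in [0, 1]")
  stopifnot(C > 0, lr > 0, max_epochs >= 1)
  fit <- cpp_train_autocm(X01, C, lr, tol, as.integer(max_epochs))
  W <- fit$W
  nms <- colnames(X01)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(X01)))
  dimnames(W) <- list(nms, nms)
  Wsym <- (W + t(W)) / 2
  diag(Wsym) <- 0
  structure(list(v = setNames(fit$v, nms), W = W, Wsym = Wsym, C = C,
                 node_names = nms, epochs_run = fit$epochs_run,
                 converged = fit$converged),
            class = "autocm_model")
}

#' @export
print.autocm_model <- function(x, ...) {
  cat("<autocm_model> ", length(x$node_names), " nodes, C = ", x$C, ", ",
      x$epochs_run, " epochs (",
      if (x$converged) "converged" else "epoch cap reached", ")\n", sep = "")
  invisible(x)
}

#' Transform Auto-CM weights into distances
#'
#' `d_ij = C - w_ij` on the symmetrized weight matrix: strongly associated
#' variable pairs become near. The diagonal is zero.
#'
#' @param m An [train_autocm()] model.
#' @return Symmetric distance matrix.
#' @export
weights_to_distances <- function(m) {
  D <- m$C - m$Wsym
  diag(D) <- 0
  D
}

#' Minimum spanning tree of a distance matrix
#'
#' Sort-based greedy construction with cycle detection (Kruskal). Ties in
#' distance are broken lexicographically on the (smaller, larger) node-name
#' pair, so the tree is reproducible.
#'
#' @param D Symmetric finite matrix with zero diagonal and named dimensions.
#' @return Data frame of `|nodes| - 1` edges: `from`, `to` (with
#'   `from < to` lexicographically), `distance`.
#' @export
minimum_spanning_tree <- function(D) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  stopifnot(nrow(D) == ncol(D), max(abs(D - t(D))) < 1e-12)
  nms <- rownames(D)
  if (is.null(nms)) nms <- paste0("V", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2L) return(data.frame(from = character(0), to = character(0),
                                distance = numeric(0)))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  from <- pmin(nms[ij[, 1]], nms[ij[, 2]])
  to <- pmax(nms[ij[, 1]], nms[ij[, 2]])
  d <- D[ij]
  ord <- order(d, from, to)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  out_from <- character(n - 1L); out_to <- character(n - 1L)
  out_d <- numeric(n - 1L); k <- 0L
  for (e in ord) {
    ri <- find(ij[e, 1]); rj <- find(ij[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      out_from[k] <- from[e]; out_to[k] <- to[e]; out_d[k] <- d[e]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) stop("distance matrix yielded a disconnected graph")
  data.frame(from = out_from, to = out_to, distance = out_d,
             stringsAsFactors = FALSE)
}

#' Build the semantic connectivity graph
#'
#' Edge strengths are the symmetrized Auto-CM weights scaled by the
#' contraction constant (`w / C`, guaranteed in \[0, 1)); the minimum
#' spanning tree of the corresponding distances `C - w` filters the complete
#' graph; hubs are the nodes of maximal tree degree (all ties reported).
#'
#' @param m An [train_autocm()] model.
#' @param node_names Optional replacement node names.
#' @return A `connectivity_graph`: list with `nodes`, `edges` (all pairs:
#'   `from`, `to`, `strength`, `in_mst`), `mst_edges` and `hubs`.
#' @export
build_connectivity_graph <- function(m, node_names = NULL) {
  nms <- if (is.null(node_names)) m$node_names else node_names
  stopifnot(length(nms) == length(m$node_names))
  S <- m$Wsym / m$C
  dimnames(S) <- list(nms, nms)
  D <- m$C - m$Wsym
  diag(D) <- 0
  dimnames(D) <- list(nms, nms)
  mst <- minimum_spanning_tree(D)
  ij <- which(upper.tri(S), arr.ind = TRUE)
  edges <- data.frame(from = pmin(nms[ij[, 1]], nms[ij[, 2]]),
                      to = pmax(nms[ij[, 1]], nms[ij[, 2]]),
                      strength = S[ij], stringsAsFactors = FALSE)
  key <- function(df) paste(df$from, df$to, sep = "\r")
  edges$in_mst <- key(edges) %in% key(mst)
  mst_edges <- edges[edges$in_mst, c("from", "to", "strength")]
  rownames(mst_edges) <- NULL
  deg <- table(c(mst_edges$from, mst_edges$to))
  hubs <- names(deg)[deg == max(deg)]
  structure(list(nodes = nms, edges = edges, mst_edges = mst_edges,
                 hubs = sort(hubs)),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat("<connectivity_graph> ", length(x$nodes), " nodes, ",
      nrow(x$mst_edges), " tree edges; hub(s): ",
      paste(x$hubs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Hop distances along the MST from one node to all others (breadth-first).
mst_hops <- function(g, from) {
  adj <- split(c(g$mst_edges$to, g$mst_edges$from),
               c(g$mst_edges$from, g$mst_edges$to))
  hops <- setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  hops[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), names(hops)[!is.na(hops)])
    if (!length(nxt)) break
    hops[nxt] <- hops[frontier[1]] + 1L
    frontier <- nxt
  }
  hops
}
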
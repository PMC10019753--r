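#' Convert a connectivity matrix to a weighted graph
#'
#' Correlation matrices contribute edge weights `|r|` (a strong negative
#' association is still coupling); PLV matrices are used as-is. The diagonal
#' is zeroed. An optional proportional threshold keeps only the strongest
#' `q` fraction of edges.
#'
#' @param cm A `connectivity_matrix`, or a plain symmetric numeric matrix with
#'   entries in `[-1, 1]`.
#' @param q Fraction of edges to keep, ranked by weight (default 1 = all).
#' @return A `weighted_graph`: list with `nodes` and the symmetric `weights`
#'   matrix (entries in `[0, 1]`, zero diagonal).
#' @export
to_weighted_graph <- function(cm, q = 1) {
  m <- if (inherits(cm, "connectivity_matrix")) {
    if (cm$method == "correlation") abs(cm$matrix) else cm$matrix
  } else {
    if (!is.matrix(m <- cm) || nrow(m) != ncol(m)) stop("need a square matrix")
    abs(m)
  }
  diag(m) <- 0
  if (q < 1) {
    w <- m[upper.tri(m)]
    keep <- max(1L, floor(q * length(w)))
    cut <- sort(w, decreasing = TRUE)[keep]
    m[m < cut] <- 0
  }
  nodes <- rownames(m) %||% sprintf("n%d", seq_len(nrow(m)))
  structure(list(nodes = nodes, weights = unname(m)), class = "weighted_graph")
}

validate_graph <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  w <- g$weights
  if (any(w < 0)) stop("negative edge weight")
  if (any(w > 1)) stop("edge weight above 1")
  if (any(diag(w) != 0)) stop("diagonal must be zero")
  if (!isTRUE(all.equal(w, t(w)))) stop("weight matrix must be symmetric")
  invisible(g)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node triangle intensity: for node `j` with binary degree `k_j`
#' (number of nonzero-weight neighbours),
#' `C_j = (1 / (k_j (k_j - 1))) * sum over neighbour pairs (k, l) of
#' 2 * (w_jk w_jl w_kl)^(1/3)`. Nodes with fewer than two neighbours get
#' `C_j = 0`. Reduces to the binary clustering coefficient on 0/1 weights.
#'
#' @param g A `weighted_graph` with weights in `[0, 1]`.
#' @return List with `per_node` (vector in `[0, 1]`) and `mean` (average over
#'   nodes with degree >= 2; 0 if no such node).
#' @export
clustering_coefficient <- function(g) {
  validate_graph(g)
  w <- g$weights
  w3 <- w^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)   # ordered triangle paths j -> k -> l -> j
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  names(cc) <- g$nodes
  eligible <- k >= 2
  list(per_node = cc, mean = if (any(eligible)) mean(cc[eligible]) else 0)
}

#' All-pairs shortest path distances (Dijkstra)
#'
#' Edge length is the reciprocal weight `d = 1/w` for `w > 0` (strong coupling
#' = short path; consistent with global efficiency being inversely related to
#' path length); zero-weight pairs have no edge. Dijkstra's algorithm is run
#' from every source; unreachable pairs get `Inf`.
#'
#' @param g A `weighted_graph`.
#' @param dist_transform `"inverse"` (`d = 1/w`, default) or `"one_minus"`
#'   (`d = 1 - w`).
#' @return Symmetric n x n distance matrix, zero diagonal.
#' @export
shortest_paths <- function(g, dist_transform = c("inverse", "one_minus")) {
  dist_transform <- match.arg(dist_transform)
  validate_graph(g)
  w <- g$weights
  n <- nrow(w)
  len <- matrix(Inf, n, n)
  pos <- w > 0
  len[pos] <- if (dist_transform == "inverse") 1 / w[pos] else 1 - w[pos]
  diag(len) <- Inf   # no self loops during relaxation
  out <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      relax <- dist[u] + len[u, ]
      upd <- !done & relax < dist
      dist[upd] <- relax[upd]
    }
    out[src, ] <- dist
  }
  diag(out) <- 0
  out
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered off-diagonal pairs with finite
#' distance. The fraction of finite pairs is reported alongside; with no
#' finite pair the length is `Inf`. Infinite (unreachable) pairs are excluded
#' from the mean rather than imputed.
#'
#' @param distances Distance matrix from [shortest_paths()].
#' @return List with `char_path_length` and `finite_pair_fraction`.
#' @export
characteristic_path_length <- function(distances) {
  off <- distances[row(distances) != col(distances)]
  fin <- is.finite(off)
  list(
    char_path_length = if (any(fin)) mean(off[fin]) else Inf,
    finite_pair_fraction = mean(fin)
  )
}

#' Graph metrics of a connectivity graph
#'
#' Bundles the two graph-theoretic features: weighted clustering coefficient
#' (local segregation) and characteristic path length (inverse proxy for
#' global efficiency).
#'
#' @param g A `weighted_graph`, or a `connectivity_matrix` (converted with
#'   [to_weighted_graph()] defaults).
#' @param dist_transform Passed to [shortest_paths()].
#' @return A `graph_metrics` object: `per_node_cc`, `mean_cc`,
#'   `char_path_length`, `finite_pair_fraction`.
#' @export
graph_metrics <- function(g, dist_transform = "inverse") {
  if (inherits(g, "connectivity_matrix")) g <- to_weighted_graph(g)
  cc <- clustering_coefficient(g)
  pl <- characteristic_path_length(shortest_paths(g, dist_transform))
  structure(list(
    per_node_cc = cc$per_node,
    mean_cc = cc$mean,
    char_path_length = pl$char_path_length,
    finite_pair_fraction = pl$finite_pair_fraction
  ), class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("<graph_metrics: mean CC=%.4f, char path length=%.4f (finite pairs: %.0f%%)>\n",
              x$mean_cc, x$char_path_length, 100 * x$finite_pair_fraction))
  invisible(x)
}

#' Weighted edge list of a graph
#'
#' @param g A `weighted_graph`.
#' @return Data frame `source`, `target`, `weight` (upper triangle, nonzero
#'   edges only), suitable for CSV export.
#' @export
graph_edges <- function(g) {
  validate_graph(g)
  ut <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  data.frame(
    source = g$nodes[ut[, 1L]],
    target = g$nodes[ut[, 2L]],
    weight = g$weights[ut],
    stringsAsFactors = FALSE
  )
}
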
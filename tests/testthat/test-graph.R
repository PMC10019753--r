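# brute-force oracles -------------------------------------------------------

# Onnela clustering via explicit triple loop over neighbour pairs
cc_oracle <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(j) {
    nb <- which(w[j, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a == b) next
      s <- s + (w[j, nb[a]] * w[j, nb[b]] * w[nb[a], nb[b]])^(1 / 3)
    }
    s / (k * (k - 1))
  }, 0)
}

# Floyd-Warshall all-pairs shortest paths on d = 1/w
fw_oracle <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

test_that("graph construction: |r| weights, zero diagonal, proportional threshold", {
  m <- matrix(1, 4, 4)
  g <- to_weighted_graph(structure(list(method = "plv", matrix = m,
                                        left = 1:2, right = 3:4),
                                   class = "connectivity_matrix"))
  expect_equal(g$weights, matrix(1, 4, 4) - diag(4))

  mr <- diag(4); mr[1, 2] <- mr[2, 1] <- -0.8
  gr <- to_weighted_graph(structure(list(method = "correlation", matrix = mr,
                                         left = 1:2, right = 3:4),
                                    class = "connectivity_matrix"))
  expect_equal(gr$weights[1, 2], 0.8)

  # q = 0.5 on 6 distinct weights keeps exactly the 3 largest (sort-and-cut)
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  w <- w + t(w)
  gq <- to_weighted_graph(w, q = 0.5)
  kept <- gq$weights[upper.tri(gq$weights)]
  expect_equal(sort(kept[kept > 0]), c(0.4, 0.5, 0.6))
  expect_equal(sum(kept > 0), 3L)
})

test_that("clustering coefficient closed forms: unit triangle and star", {
  tri <- fake_graph(matrix(1, 3, 3))
  cc <- clustering_coefficient(tri)
  expect_equal(unname(cc$per_node), rep(1, 3))
  expect_equal(cc$mean, 1)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  ccs <- clustering_coefficient(fake_graph(star))
  expect_equal(unname(ccs$per_node), rep(0, 4))

  neg <- fake_graph(matrix(1, 3, 3))
  neg$weights[1, 2] <- neg$weights[2, 1] <- -0.5
  expect_error(clustering_coefficient(neg), "negative")
})

test_that("clustering coefficient matches triangle enumeration on random graphs", {
  set.seed(11)
  for (i in 1:100) {
    g <- random_graph(sample(3:6, 1), density = runif(1, 0.3, 1))
    cc <- clustering_coefficient(g)
    expect_equal(unname(cc$per_node), cc_oracle(g$weights), tolerance = 1e-12)
  }
})

test_that("clustering reduces to the binary coefficient on 0/1 weights", {
  set.seed(12)
  for (i in 1:20) {
    g <- random_graph(6, density = 0.5)
    g$weights <- (g$weights > 0) * 1
    cc <- clustering_coefficient(g)
    # binary oracle: triangles / possible wedges
    a <- g$weights
    bin <- vapply(1:6, function(j) {
      nb <- which(a[j, ] > 0); k <- length(nb)
      if (k < 2) return(0)
      sum(a[nb, nb]) / (k * (k - 1))
    }, 0)
    expect_equal(unname(cc$per_node), bin, tolerance = 1e-12)
  }
})

test_that("Dijkstra distances: detours, complete graphs, disconnection", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 0.25
  d <- shortest_paths(fake_graph(w))
  expect_equal(d[1, 3], 2)         # 1 + 1 via the middle node beats 1/0.25 = 4

  dc <- shortest_paths(fake_graph(matrix(1, 5, 5)))
  expect_equal(unname(dc), matrix(1, 5, 5) - diag(5))

  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  dd <- shortest_paths(fake_graph(two))
  expect_equal(dd[1, 3], Inf)
  expect_equal(dd[1, 2], 1)
})

test_that("Dijkstra agrees with Floyd-Warshall on random graphs", {
  set.seed(13)
  for (i in 1:100) {
    g <- random_graph(sample(3:6, 1), density = runif(1, 0.2, 1))
    expect_equal(unname(shortest_paths(g)), fw_oracle(g$weights))
  }
})

test_that("Dijkstra agrees with igraph on a batch of graphs", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (i in 1:20) {
    g <- random_graph(6, density = 0.6)
    adj <- ifelse(g$weights > 0, 1 / g$weights, 0)   # edge lengths d = 1/w
    ig <- igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected", weighted = TRUE, diag = FALSE)
    dig <- igraph::distances(ig, algorithm = "dijkstra")
    expect_equal(unname(shortest_paths(g)), unname(dig))
  }
})

test_that("raising a weight never increases any distance", {
  set.seed(15)
  for (i in 1:20) {
    g <- random_graph(6, density = 0.6)
    d0 <- shortest_paths(g)
    e <- which(upper.tri(g$weights), arr.ind = TRUE)
    pick <- e[sample(nrow(e), 1), ]
    g2 <- g
    g2$weights[pick[1], pick[2]] <- g2$weights[pick[2], pick[1]] <-
      min(1, g$weights[pick[1], pick[2]] + runif(1, 0.1, 0.5))
    d1 <- shortest_paths(g2)
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("characteristic path length averages finite ordered pairs", {
  dc <- shortest_paths(fake_graph(matrix(1, 5, 5)))
  pl <- characteristic_path_length(dc)
  expect_equal(pl$char_path_length, 1)
  expect_equal(pl$finite_pair_fraction, 1)

  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 0.5
  pl2 <- characteristic_path_length(shortest_paths(fake_graph(two)))
  expect_equal(pl2$char_path_length, 2)           # the 4 finite pairs, d = 1/0.5
  expect_equal(pl2$finite_pair_fraction, 4 / 12)

  empty <- characteristic_path_length(shortest_paths(fake_graph(matrix(0, 3, 3))))
  expect_equal(empty$char_path_length, Inf)
  expect_equal(empty$finite_pair_fraction, 0)

  # stronger graph (elementwise >= weights) has no longer characteristic path
  set.seed(16)
  g <- random_graph(6, density = 0.7)
  g2 <- g; g2$weights <- pmin(g$weights * 1.5, 1)
  pla <- characteristic_path_length(shortest_paths(g))
  plb <- characteristic_path_length(shortest_paths(g2))
  expect_lte(plb$char_path_length, pla$char_path_length)

  # 5-node random graph equals the Floyd-Warshall all-pairs average
  g5 <- random_graph(5, density = 0.8)
  d5 <- fw_oracle(g5$weights)
  off <- d5[row(d5) != col(d5)]
  expect_equal(characteristic_path_length(shortest_paths(g5))$char_path_length,
               mean(off[is.finite(off)]))
})

test_that("graph_metrics bundles both measures; edge list round-trips weights", {
  g <- random_graph(6, density = 0.8)
  gm <- graph_metrics(g)
  expect_s3_class(gm, "graph_metrics")
  expect_equal(gm$mean_cc, clustering_coefficient(g)$mean)
  expect_equal(gm$char_path_length,
               characteristic_path_length(shortest_paths(g))$char_path_length)

  el <- graph_edges(g)
  expect_equal(nrow(el), sum(g$weights[upper.tri(g$weights)] > 0))
  i <- match(el$source[1], g$nodes); j <- match(el$target[1], g$nodes)
  expect_equal(el$weight[1], g$weights[i, j])
})
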
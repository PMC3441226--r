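# Shared helpers: random structure generators and independent oracles.

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  M <- matrix(runif(n * n, 0.05, 1), n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  dimnames(D) <- list(labels, labels)
  D
}

# additive distance matrix from a random tree; returns both
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  D <- cophenetic(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# exact hypergeometric upper tail by exhaustive enumeration of all
# C(n, c) draws from a labeled population with m successes
hypergeom_upper_enum <- function(n, m, c, k) {
  if (k == 0) return(1)
  if (c == 0) return(0)
  draws <- utils::combn(n, c)
  hits <- colSums(draws <= m)  # successes are items 1..m
  mean(hits >= k)
}

# trimmed mean with floor(trim * N) order statistics removed at each end
trimmed_mean <- function(v, trim = 0.02) {
  k <- floor(trim * length(v))
  s <- sort(v)
  if (k > 0) s <- s[(k + 1):(length(v) - k)]
  mean(s)
}

expect_same_topology <- function(t1, t2) {
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
}
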
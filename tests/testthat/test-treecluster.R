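test_that("to_distance is 1 - R with zero diagonal", {
  R <- matrix(c(1, 0.25, -1, 0.25, 1, 0, -1, 0, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  D <- to_distance(R)
  expect_equal(D["a", "b"], 0.75)
  expect_equal(D["a", "c"], 2)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_error(to_distance(matrix(c(1, 2, 3, 1), 2)), "unit diagonal")
})

test_that("2- and 3-leaf joins use the closed-form branch lengths", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  tr <- neighbour_joining(D)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(0.2, 0.2))

  # three-point formulas: a = (d_ab + d_ac - d_bc)/2, etc.
  d_ab <- 0.6; d_ac <- 0.8; d_bc <- 0.9
  D3 <- matrix(c(0, d_ab, d_ac, d_ab, 0, d_bc, d_ac, d_bc, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbour_joining(D3)
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[["A"]], (d_ab + d_ac - d_bc) / 2)
  expect_equal(bl[["B"]], (d_ab + d_bc - d_ac) / 2)
  expect_equal(bl[["C"]], (d_ac + d_bc - d_ab) / 2)
  expect_error(neighbour_joining(D3[1, 1, drop = FALSE]), "at least 2")
})

test_that("NJ topology matches the independent ape oracle on random matrices", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    D <- random_distance_matrix(n)
    mine <- neighbour_joining(D, clamp_negative = FALSE)
    oracle <- ape::nj(as.dist(D))
    expect_same_topology(mine, oracle)
  }
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(17)
  for (n in c(4, 6, 8, 12, 16)) {
    gen <- random_additive_matrix(n)
    tr <- neighbour_joining(gen$D)
    expect_same_topology(tr, gen$tree)
    # reconstructed path lengths reproduce the input matrix
    C <- cophenetic(tr)[rownames(gen$D), colnames(gen$D)]
    expect_lt(max(abs(C - gen$D)), 1e-9)
  }
})

test_that("NJ output is a valid rooted-with-trifurcation phylo", {
  set.seed(4)
  D <- random_distance_matrix(8)
  tr <- neighbour_joining(D)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, rownames(D))
  expect_true(all(tr$edge.length >= 0))
  root <- ape::Ntip(tr) + 1L
  expect_equal(sum(tr$edge[, 1] == root), 3L)  # trifurcating root
  kids <- table(tr$edge[, 1])
  expect_true(all(kids[names(kids) != root] == 2))  # binary elsewhere
})

test_that("negative branch lengths are clamped, preserving path lengths", {
  # classic non-additive configuration that yields a negative NJ branch
  D <- matrix(c(0, 5, 9, 9, 5, 0, 4, 6, 9, 4, 0, 2, 9, 6, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4])) / 10
  raw <- neighbour_joining(D, clamp_negative = FALSE)
  suppressMessages(clamped <- neighbour_joining(D, clamp_negative = TRUE))
  if (any(raw$edge.length < 0)) {
    expect_true(all(clamped$edge.length >= 0))
    expect_equal(cophenetic(clamped)[LETTERS[1:4], LETTERS[1:4]],
                 cophenetic(raw)[LETTERS[1:4], LETTERS[1:4]],
                 tolerance = 1e-12)
  }
  set.seed(31)
  for (i in 1:20) {
    Dr <- random_distance_matrix(7)
    suppressMessages(tr <- neighbour_joining(Dr))
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("midpoint rooting returns a bifurcating root", {
  skip_if_not_installed("phangorn")
  D <- random_distance_matrix(6)
  tr <- neighbour_joining(D, rooting = "midpoint")
  expect_true(ape::is.rooted(tr))
})

test_that("neighborhood follows path-length semantics on a cherry", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:0.1,B:0.2);", f)
  tr <- read_newick(f)
  expect_equal(neighborhood(tr, "A", 0)$members, "A")
  expect_setequal(neighborhood(tr, "A", 0.1)$members, c("A", "B"))
  expect_equal(neighborhood(tr, "A", 0.05)$members, "A")
  expect_error(neighborhood(tr, "Z", 1), "not in tree")
})

test_that("neighborhood is monotone in h and saturates at all leaves", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    tr <- neighbour_joining(random_distance_matrix(n))
    q <- sample(tr$tip.label, 1)
    hs <- sort(runif(10, 0, 3))
    prev <- character(0)
    for (h in hs) {
      cur <- neighborhood(tr, q, h)$members
      expect_true(q %in% cur)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    expect_setequal(neighborhood(tr, q, sum(tr$edge.length))$members,
                    tr$tip.label)
  }
})

test_that("planted modules form clades and tree_ranked_list orders by r", {
  spec <- fixture_spec(modules = list(
    list(size = 5, latent_strength = 0.9, term = "MODA"),
    list(size = 6, latent_strength = 0.9, term = "MODB")), seed = 9)
  fx <- make_expression(spec)
  R <- correlation_matrix(fx$matrix)
  tr <- neighbour_joining(to_distance(R))
  expect_true(ape::is.monophyletic(tr, fx$modules$MODA))
  expect_true(ape::is.monophyletic(tr, fx$modules$MODB))

  q <- fx$modules$MODA[1]
  trl <- tree_ranked_list(tr, q, 0.5, R)
  expect_equal(trl$probe_id[1], q)
  expect_equal(trl$r[1], 1)
  expect_true(all(diff(trl$r[-1]) <= 0))
  # ordering equals ranked_list restricted to the neighbourhood
  rl <- ranked_list(q, R, k = nrow(R))
  expect_equal(trl$probe_id[-1],
               rl$probe_y[rl$probe_y %in% trl$probe_id])
  # size-1 neighbourhood
  one <- tree_ranked_list(tr, q, 0, R)
  expect_equal(one$probe_id, q)
})
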
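test_that("intensity range QC passes [0, 65535] inclusive and flags indices", {
  expect_true(qc_intensity_range(
    intensity_vector("s1", c(0, 65535, 123.5)))$pass)
  r <- qc_intensity_range(intensity_vector("s2", c(-1, 10)))
  expect_false(r$pass)
  expect_equal(r$offending, 1L)
  r <- qc_intensity_range(intensity_vector("s3", c(10, 65536)))
  expect_false(r$pass)
  expect_equal(r$offending, 2L)
  expect_error(intensity_vector("s4", numeric(0)), "non-empty")
})

test_that("intensity signature matches an independent hash oracle", {
  # frozen from python hashlib/zlib on the serialization "065535123.5"
  sig <- intensity_signature(intensity_vector("s", c(0, 65535, 123.5)))
  expect_equal(nchar(sig), 80L)
  expect_equal(substr(sig, 1, 32), "aaf2800d6e8ed06af0655868a345d950")
  expect_equal(substr(sig, 33, 72),
               "e06015a2d2aa9ac9b9ab2b18899a81f344739c4e")
  expect_equal(substr(sig, 73, 80), "ff4dce00")
})

test_that("signatures are deterministic and sensitive to single values", {
  set.seed(5)
  v <- round(runif(50, 0, 65535), 1)
  a <- intensity_vector("a", v)
  expect_identical(intensity_signature(a),
                   intensity_signature(intensity_vector("b", v)))
  for (i in sample(50, 20)) {
    w <- v
    w[i] <- w[i] + 0.1
    expect_false(intensity_signature(intensity_vector("c", w)) ==
                   intensity_signature(a))
  }
})

test_that("deduplicate keeps one representative per signature", {
  v1 <- c(1, 2, 3)
  samples <- list(intensity_vector("GSM2", v1),
                  intensity_vector("GSM1", v1),
                  intensity_vector("GSM3", c(4, 5, 6)))
  res <- deduplicate(samples)
  ids <- vapply(res$unique, `[[`, character(1), "sample_id")
  expect_setequal(ids, c("GSM1", "GSM3"))   # lexicographically smallest kept
  expect_equal(unname(sort(lengths(res$groups))), c(1L, 2L))
  # all distinct -> all retained
  res2 <- deduplicate(list(intensity_vector("a", 1),
                           intensity_vector("b", 2)))
  expect_length(res2$unique, 2L)
  # never removes a sample without an identical-signature partner
  expect_true(all(lengths(res2$groups) == 1L))
})

test_that("balanced selection splits evenly and handles exhausted tissues", {
  mk <- function(id, t, s) intensity_vector(id, 0, tissue = t, series = s)
  # 2 tissues x 10, target 10 -> 5 + 5
  samples <- c(lapply(1:10, function(i) mk(sprintf("A%02d", i), "liver", "G1")),
               lapply(1:10, function(i) mk(sprintf("B%02d", i), "brain", "G2")))
  sel <- balanced_selection(samples, 10)
  tt <- table(substr(sel, 1, 1))
  expect_equal(unname(tt[c("A", "B")]), c(5L, 5L), ignore_attr = TRUE)
  # target >= total -> everything
  expect_length(balanced_selection(samples, 99), 20L)
  # hand-derived: tissues sized (2, 10, 10), target 12 -> (2, 5, 5)
  samples3 <- c(lapply(1:2, function(i) mk(sprintf("X%02d", i), "t1", "G")),
                lapply(1:10, function(i) mk(sprintf("Y%02d", i), "t2", "G")),
                lapply(1:10, function(i) mk(sprintf("Z%02d", i), "t3", "G")))
  sel3 <- balanced_selection(samples3, 12)
  expect_equal(unname(table(substr(sel3, 1, 1))), c(2L, 5L, 5L),
               ignore_attr = TRUE)
  expect_error(balanced_selection(samples3, 0), "positive")
})

test_that("balanced selection is invariant to input order and balances series", {
  set.seed(8)
  mk <- function(id, t, s) intensity_vector(id, 0, tissue = t, series = s)
  samples <- list()
  for (t in c("ta", "tb", "tc")) {
    for (s in c("G1", "G2", "G3")) {
      for (i in 1:4) {
        samples[[length(samples) + 1]] <-
          mk(paste(t, s, i, sep = "_"), t, s)
      }
    }
  }
  sel <- balanced_selection(samples, 15)
  sel_shuffled <- balanced_selection(sample(samples), 15)
  expect_identical(sel, sel_shuffled)
  parts <- strsplit(sel, "_")
  tis <- vapply(parts, `[`, character(1), 1)
  ser <- vapply(parts, `[`, character(1), 2)
  expect_lte(diff(range(table(tis))), 1L)
  for (t in unique(tis)) {
    expect_lte(diff(range(table(ser[tis == t]))), 1L)
  }
})

test_that("control probe sets are dropped, order preserved", {
  vals <- matrix(1:6, 3, 2,
                 dimnames = list(c("AFFX-1", "200725_x_at", "affx_like_at"),
                                 c("S1", "S2")))
  m <- drop_control_probesets(expression_matrix(vals))
  # prefix match is case-sensitive: lowercase id survives
  expect_equal(probe_ids(m), c("200725_x_at", "affx_like_at"))
  vals2 <- matrix(1:2, 1, 2, dimnames = list("AFFX-A", c("S1", "S2")))
  expect_error(drop_control_probesets(expression_matrix(vals2)), "empty")
  m3 <- expression_matrix(vals[-1, , drop = FALSE])
  expect_equal(probe_ids(drop_control_probesets(m3)), probe_ids(m3))
})

test_that("scaling factor hits the trimmed-mean target", {
  expect_equal(scaling_factor(rep(250, 100)), 2.0)
  v <- c(rep(500, 98), 0, 1e6)  # trimmed mean already 500
  expect_equal(scaling_factor(v), 1.0)
  set.seed(13)
  x <- exp(rnorm(1000, log(300), 0.8))
  f <- scaling_factor(x)
  expect_equal(trimmed_mean(x * f), 500, tolerance = 1e-9)
  expect_error(scaling_factor(rep(0, 100)), "not positive")
  expect_error(scaling_factor(c(1, 2)), "at least 3")
})

test_that("round_to_half rounds to the nearest 0.5, midpoints up", {
  expect_equal(round_to_half(c(123.2, 123.26, 0.75, 0.5, 1.24)),
               c(123.0, 123.5, 1.0, 0.5, 1.0))
  x <- round_to_half(runif(100, 0, 1000))
  expect_true(all(x * 2 == floor(x * 2)))
})

test_that("normalize_matrix scales each sample to the target and is stable", {
  vals <- matrix(250, 5, 2, dimnames = list(sprintf("p%d_at", 1:5),
                                            c("S1", "S2")))
  vals[1, ] <- c(260, 240)  # avoid zero variance concerns downstream
  m <- normalize_matrix(expression_matrix(vals))
  expect_equal(dim(m$values), dim(vals))
  expect_true(all(abs(m$values - 500) <= 25))

  set.seed(21)
  vals <- matrix(exp(rnorm(500, log(400), 0.5)), 50, 10,
                 dimnames = list(sprintf("p%02d_at", 1:50),
                                 sprintf("S%02d", 1:10)))
  m <- normalize_matrix(expression_matrix(vals))
  tm <- apply(m$values, 2, trimmed_mean)
  expect_true(all(abs(tm - 500) <= 0.5))
  # idempotent up to rounding on the 0.5 grid
  m2 <- normalize_matrix(m)
  expect_lte(max(abs(m2$values - m$values)), 0.5)
})
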
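# Pairwise Pearson correlation with Student-t significance, Bonferroni
# correction, and r-value-ranked coexpression lists.

#' Pearson correlation coefficient between two signal profiles
#'
#' Computed either as the covariance divided by the product of the
#' standard deviations (`method = "covariance"`) or, equivalently, as the
#' mean cross-product of the standardized variables
#' (`method = "standardized"`). The two routes agree to floating-point
#' precision and are cross-checked in the test suite.
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero
#'   variance.
#' @param method computation route; the results are mathematically
#'   identical.
#' @return correlation in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(x, y, method = c("covariance", "standardized")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y))
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx2 <- sum(dx^2)
  sy2 <- sum(dy^2)
  if (sx2 == 0 || sy2 == 0) {
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  }
  r <- if (method == "covariance") {
    sum(dx * dy) / sqrt(sx2 * sy2)
  } else {
    zx <- dx / sqrt(sx2 / n)   # population standardization
    zy <- dy / sqrt(sy2 / n)
    sum(zx * zy) / n
  }
  max(-1, min(1, r))
}

#' Student-t statistic for a correlation
#'
#' Under the null of no correlation, `t = r * sqrt(nu) / sqrt(1 - r^2)`
#' follows a Student-t distribution with `nu = n - 2` degrees of freedom.
#'
#' @param r correlation in (-1, 1); `|r| = 1` yields `Inf` with the sign
#'   of `r` (perfect association).
#' @param n sample count (>= 3).
#' @return t statistic (same sign as `r`).
#' @export
t_statistic <- function(r, n) {
  stopifnot(is.numeric(r), abs(r) <= 1, n >= 3)
  nu <- n - 2
  ifelse(abs(r) == 1, sign(r) * Inf, r * sqrt(nu) / sqrt(1 - r^2))
}

#' Two-sided Student-t significance
#'
#' The two-sided tail probability `A(|t| | nu)` of the Student-t
#' distribution: the p-value of the correlation test.
#'
#' @param t t statistic; `Inf` yields p = 0.
#' @param nu degrees of freedom (>= 1).
#' @return p-value in \[0, 1\]; `p_two_sided(0, nu)` is 1.
#' @export
p_two_sided <- function(t, nu) {
  if (!is.numeric(nu) || any(nu < 1)) {
    stop("'nu' must be >= 1", call. = FALSE)
  }
  2 * stats::pt(abs(t), df = nu, lower.tail = FALSE)
}

#' Bonferroni-corrected e-value
#'
#' `e = n_tests * p`, capped at 1 whenever the product exceeds one.
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param n_tests number of tests in the family (>= 1); for an
#'   all-against-all screen of m probe sets this is `m * (m - 1) / 2`.
#' @return corrected e-value(s) in \[0, 1\].
#' @examples
#' bonferroni(0.05, 1000)  # capped at 1
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), n_tests >= 1)
  pmin(n_tests * p, 1)
}

#' All-against-all correlation matrix
#'
#' Symmetric matrix of Pearson correlations between every pair of
#' probe-set signal profiles (rows of the expression matrix). Probe sets
#' with zero variance have no defined correlation and are excluded with a
#' warning naming them.
#'
#' @param m an [expression_matrix()] (or a plain numeric matrix with
#'   probe-set rownames), >= 2 probe sets and >= 3 samples.
#' @return symmetric numeric matrix with unit diagonal, probe-set IDs as
#'   dimnames, and attribute `"n_samples"`.
#' @export
correlation_matrix <- function(m) {
  vals <- if (inherits(m, "expr_matrix")) m$values else m
  stopifnot(is.matrix(vals), is.numeric(vals))
  if (ncol(vals) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(vals, 1, stats::sd)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance probe set(s): ",
            paste(utils::head(rownames(vals)[v == 0], 5), collapse = ", "),
            call. = FALSE)
    vals <- vals[v > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2) stop("need at least 2 probe sets", call. = FALSE)
  n <- ncol(vals)
  ctr <- vals - rowMeans(vals)
  z <- ctr / sqrt(rowSums(ctr^2) / n)  # standardized rows (population sd)
  R <- tcrossprod(z) / n               # mean cross-product of z-scores
  R <- (R + t(R)) / 2
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  attr(R, "n_samples") <- n
  R
}

#' Full correlation statistics for one probe-set pair
#'
#' @param r correlation.
#' @param n sample count.
#' @param n_tests Bonferroni family size.
#' @return list with `r`, `t`, `p`, `e`, `n`, `nu`. `|r| = 1` is reported
#'   with p = e = 0 (perfect association).
#' @export
correlation_record <- function(r, n, n_tests) {
  t <- t_statistic(r, n)
  p <- if (is.infinite(t)) 0 else p_two_sided(t, n - 2)
  list(r = r, t = t, p = p, e = bonferroni(p, n_tests),
       n = as.integer(n), nu = as.integer(n - 2))
}

#' r-value-ranked coexpression list for a driver probe set
#'
#' The k probe sets most closely correlated (or anti-correlated) with the
#' query, with full correlation statistics. The query's own self-pair is
#' excluded; ties in r are broken by probe-set ID.
#'
#' @param q query (driver) probe-set ID, present in `R`.
#' @param R correlation matrix from [correlation_matrix()].
#' @param k number of probe sets to return (>= 1; capped at the number of
#'   other probe sets).
#' @param direction `"correlated"` (largest r first) or
#'   `"anticorrelated"` (smallest r first).
#' @param n_tests Bonferroni family size; defaults to the number of
#'   unordered probe pairs in `R`.
#' @return data.frame with columns `probe_x` (query), `probe_y`, `r`,
#'   `t`, `p`, `e`, ordered by rank.
#' @export
ranked_list <- function(q, R, k = 50,
                        direction = c("correlated", "anticorrelated"),
                        n_tests = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(R), k >= 1)
  ids <- rownames(R)
  if (!q %in% ids) stop("query probe set not in matrix: ", q, call. = FALSE)
  n <- attr(R, "n_samples")
  if (is.null(n)) stop("correlation matrix lacks 'n_samples'", call. = FALSE)
  m <- length(ids)
  if (is.null(n_tests)) n_tests <- m * (m - 1) / 2
  r <- R[q, setdiff(ids, q)]
  ord <- if (direction == "correlated") {
    order(-r, names(r))
  } else {
    order(r, names(r))
  }
  top <- r[ord][seq_len(min(k, length(r)))]
  recs <- lapply(unname(top), correlation_record, n = n, n_tests = n_tests)
  data.frame(probe_x = q,
             probe_y = names(top),
             r = vapply(recs, `[[`, numeric(1), "r"),
             t = vapply(recs, `[[`, numeric(1), "t"),
             p = vapply(recs, `[[`, numeric(1), "p"),
             e = vapply(recs, `[[`, numeric(1), "e"),
             row.names = NULL, stringsAsFactors = FALSE)
}
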
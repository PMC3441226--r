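# Quality control, duplicate detection, balanced sample selection and
# trimmed-mean signal scaling for probe-set signal matrices.

#' Construct a raw intensity vector
#'
#' Holds the raw probe intensities of one array sample plus the tissue and
#' series labels used for balanced selection. Intensities are raw chip
#' values, valid only within \[0, 65535\].
#'
#' @param sample_id sample identifier (e.g. a GSM accession).
#' @param values numeric vector of raw probe intensities.
#' @param tissue,series tissue/organ and sample-series labels.
#' @return an object of class `"intensity_vector"`.
#' @export
intensity_vector <- function(sample_id, values, tissue = "", series = "") {
  stopifnot(is.character(sample_id), length(sample_id) == 1, nzchar(sample_id),
            is.numeric(values))
  if (length(values) == 0) {
    stop("intensity vector must be non-empty", call. = FALSE)
  }
  structure(list(sample_id = sample_id, values = as.numeric(values),
                 tissue = as.character(tissue), series = as.character(series)),
            class = "intensity_vector")
}

#' Intensity-range quality control
#'
#' A sample passes QC iff every raw intensity lies within the acceptable
#' chip value range \[0, 65535\] (inclusive).
#'
#' @param v an [intensity_vector()].
#' @return list with elements `pass` (logical) and `offending` (integer
#'   indices of out-of-range values, empty when `pass`).
#' @examples
#' qc_intensity_range(intensity_vector("s1", c(0, 65535, 123.5)))$pass
#' @export
qc_intensity_range <- function(v) {
  stopifnot(inherits(v, "intensity_vector"))
  bad <- which(!is.finite(v$values) | v$values < 0 | v$values > 65535)
  list(pass = length(bad) == 0L, offending = bad)
}

# Canonical serialization of intensities before hashing: each value as its
# shortest exact decimal (integers without ".0"), concatenated with no
# separator. Internally consistent; not byte-identical to any external tool.
serialize_intensities <- function(values) {
  s <- vapply(values, function(x) {
    if (is.finite(x) && x == trunc(x) && abs(x) < 1e15) {
      sprintf("%.0f", x)
    } else {
      format(x, digits = 15, trim = TRUE, scientific = FALSE,
             drop0trailing = TRUE)
    }
  }, character(1))
  paste(s, collapse = "")
}

#' Hash signature of a raw intensity vector
#'
#' Concatenates all intensity values into a single string and hashes it
#' with MD5, SHA-1 and CRC32; the three lowercase hex digests are
#' concatenated (in that order, CRC32 zero-padded to 8 digits) into an
#' 80-character signature used to detect duplicate samples.
#'
#' @param v an [intensity_vector()] that passed QC.
#' @return 80-character hex string.
#' @export
intensity_signature <- function(v) {
  stopifnot(inherits(v, "intensity_vector"))
  s <- serialize_intensities(v$values)
  md5 <- digest::digest(s, algo = "md5", serialize = FALSE)
  sha1 <- digest::digest(s, algo = "sha1", serialize = FALSE)
  crc <- digest::digest(s, algo = "crc32", serialize = FALSE)
  crc <- paste0(strrep("0", 8L - nchar(crc)), crc)
  sig <- paste0(md5, sha1, crc)
  stopifnot(nchar(sig) == 80L)
  sig
}

#' Remove duplicate samples by hash signature
#'
#' Groups samples by [intensity_signature()]; one representative per
#' signature is kept (the lexicographically smallest sample ID).
#'
#' @param samples list of [intensity_vector()] objects, all QC-passed.
#' @return list with `unique` (list of representatives, input order of
#'   first appearance) and `groups` (named list mapping each signature to
#'   the sorted member sample IDs; groups of size > 1 are duplicates).
#' @export
deduplicate <- function(samples) {
  stopifnot(is.list(samples),
            all(vapply(samples, inherits, logical(1), "intensity_vector")))
  sigs <- vapply(samples, intensity_signature, character(1))
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  groups <- lapply(split(ids, sigs), sort)
  keep_ids <- vapply(groups, `[`, character(1), 1)
  keep <- ids %in% keep_ids
  list(unique = samples[keep], groups = groups)
}

#' Tissue- and series-balanced sample selection
#'
#' Selects `target_n` samples as evenly as possible among tissues and,
#' within each tissue, among sample series: repeatedly pick from the
#' non-exhausted tissue with the fewest selected samples (ties broken
#' lexicographically by tissue name), within it from the series with the
#' fewest selected (ties lexicographic), and within the series the
#' smallest remaining sample ID. Fully deterministic and invariant to
#' input order.
#'
#' @param samples list of deduplicated [intensity_vector()] objects.
#' @param target_n number of samples to select (>= 1).
#' @return character vector of selected sample IDs, sorted.
#' @export
balanced_selection <- function(samples, target_n) {
  stopifnot(is.list(samples))
  if (!is.numeric(target_n) || length(target_n) != 1 || target_n < 1) {
    stop("'target_n' must be a positive integer", call. = FALSE)
  }
  target_n <- as.integer(target_n)
  df <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    tissue = vapply(samples, `[[`, character(1), "tissue"),
    series = vapply(samples, `[[`, character(1), "series"),
    stringsAsFactors = FALSE)
  df <- df[order(df$tissue, df$series, df$sample_id), ]
  df$taken <- FALSE
  n_take <- min(target_n, nrow(df))
  tissues <- sort(unique(df$tissue))
  t_count <- stats::setNames(integer(length(tissues)), tissues)
  s_count <- new.env(parent = emptyenv())
  selected <- character(n_take)
  for (pick in seq_len(n_take)) {
    avail_t <- tissues[vapply(tissues, function(tt)
      any(!df$taken[df$tissue == tt]), logical(1))]
    tt <- avail_t[which.min(t_count[avail_t])]  # ties: first = lexicographic
    rows <- which(df$tissue == tt & !df$taken)
    ser <- sort(unique(df$series[rows]))
    sc <- vapply(ser, function(s) {
      key <- paste0(tt, "\r", s)
      if (is.null(s_count[[key]])) 0L else s_count[[key]]
    }, integer(1))
    ss <- ser[which.min(sc)]
    cand <- rows[df$series[rows] == ss]
    row <- cand[order(df$sample_id[cand])[1]]
    df$taken[row] <- TRUE
    selected[pick] <- df$sample_id[row]
    t_count[tt] <- t_count[tt] + 1L
    key <- paste0(tt, "\r", ss)
    s_count[[key]] <- (if (is.null(s_count[[key]])) 0L else s_count[[key]]) + 1L
  }
  sort(selected)
}

#' Drop Affymetrix control probe sets
#'
#' Removes every probe set whose ID starts with `"AFFX"` (the Affymetrix
#' hybridization/housekeeping controls); the order of the remaining probe
#' sets is preserved.
#'
#' @param m an [expression_matrix()].
#' @return an `expr_matrix` without control probe sets.
#' @export
drop_control_probesets <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  keep <- !is_control_probeset(probe_ids(m))
  if (!any(keep)) {
    stop("all probe sets are AFFX controls; empty matrix", call. = FALSE)
  }
  expression_matrix(m$values[keep, , drop = FALSE],
                    tissue = m$sample_meta$tissue,
                    series = m$sample_meta$series)
}

#' Trimmed-mean scaling factor
#'
#' The per-chip scaling factor of the standard Affymetrix procedure:
#' remove the top and bottom `trim_fraction` of signal values (the
#' `floor(trim_fraction * N)` highest and lowest order statistics), then
#' return the factor that adjusts the mean of the remaining values to
#' `target`.
#'
#' @param sample_values numeric vector of signal values for one sample.
#' @param trim_fraction fraction trimmed at each end (default 2%).
#' @param target target trimmed mean (default 500).
#' @return positive scaling factor.
#' @examples
#' scaling_factor(rep(250, 100))  # 2
#' @export
scaling_factor <- function(sample_values, trim_fraction = 0.02, target = 500) {
  stopifnot(is.numeric(sample_values), trim_fraction >= 0, trim_fraction < 0.5,
            target > 0)
  n <- length(sample_values)
  k <- floor(trim_fraction * n)
  if (n - 2 * k < 3) {
    stop("need at least 3 values after trimming", call. = FALSE)
  }
  v <- sort(sample_values)
  if (k > 0) v <- v[(k + 1):(n - k)]
  mu <- mean(v)
  if (mu <= 0) {
    stop("trimmed mean is not positive; scaling factor undefined",
         call. = FALSE)
  }
  target / mu
}

#' Round to the nearest 0.5
#'
#' Rounds each value to the nearest multiple of 0.5; exact midpoints
#' (x = 0.25 mod 0.5) round half away from zero.
#'
#' @param x numeric vector of finite values.
#' @return numeric vector of multiples of 0.5.
#' @examples
#' round_to_half(c(123.2, 123.26, 0.75))  # 123.0 123.5 1.0
#' @export
round_to_half <- function(x) {
  stopifnot(all(is.finite(x)))
  sign(x) * floor(2 * abs(x) + 0.5) / 2
}

#' Normalize an expression matrix by per-sample trimmed-mean scaling
#'
#' For each sample (column): compute the [scaling_factor()] (2% trim,
#' target 500 by default), multiply all signals by it, then round every
#' value to the nearest 0.5. Control probe sets should already have been
#' dropped with [drop_control_probesets()].
#'
#' @param m an [expression_matrix()].
#' @param trim_fraction,target passed to [scaling_factor()].
#' @return normalized `expr_matrix`, same dimensions.
#' @export
normalize_matrix <- function(m, trim_fraction = 0.02, target = 500) {
  stopifnot(inherits(m, "expr_matrix"))
  vals <- m$values
  for (j in seq_len(ncol(vals))) {
    f <- scaling_factor(vals[, j], trim_fraction, target)
    vals[, j] <- round_to_half(vals[, j] * f)
  }
  expression_matrix(vals, tissue = m$sample_meta$tissue,
                    series = m$sample_meta$series)
}
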
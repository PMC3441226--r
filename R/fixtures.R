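# Deterministic synthetic-data generation: expression matrices with
# planted coexpression modules, annotation catalogs with planted enriched
# terms, intensity sets with planted duplicates, and promoters with
# planted motif sites. Every generator is a pure function of its spec
# (seed included), so ground truth is always available for scoring
# recovery without external data.

#' Specification of a synthetic data set
#'
#' @param n_probes number of probe sets.
#' @param n_samples number of samples.
#' @param modules list of planted coexpression modules, each a list with
#'   `size` (members), `latent_strength` (target within-module Pearson r,
#'   in (0, 1)) and `term` (the annotation term shared by the members).
#' @param noise_sd per-probe log-scale noise standard deviation.
#' @param seed RNG seed; identical specs produce identical outputs.
#' @param duplicates number of exact duplicate samples to plant in
#'   [make_intensity_set()].
#' @param tissues list of tissue descriptors, each a list with `name`
#'   and `series_counts` (named integer vector: series -> sample count).
#' @return a validated list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_probes = 50, n_samples = 100,
                         modules = list(list(size = 5,
                                             latent_strength = 0.9,
                                             term = "PLANTED")),
                         noise_sd = 0.1, seed = 1, duplicates = 0,
                         tissues = list(
                           list(name = "liver",
                                series_counts = c(GSE1 = 5, GSE2 = 5)),
                           list(name = "brain",
                                series_counts = c(GSE3 = 5, GSE4 = 5)))) {
  stopifnot(n_probes >= 2, n_samples >= 3, noise_sd > 0, duplicates >= 0)
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  rho <- vapply(modules, `[[`, numeric(1), "latent_strength")
  if (sum(sizes) > n_probes) {
    stop("module sizes exceed the number of probe sets", call. = FALSE)
  }
  if (any(rho <= 0 | rho >= 1)) {
    stop("latent_strength must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_probes = as.integer(n_probes),
                 n_samples = as.integer(n_samples), modules = modules,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 duplicates = as.integer(duplicates), tissues = tissues),
            class = "fixture_spec")
}

# sample tissue/series labels recycled over n samples
spec_sample_meta <- function(spec, n) {
  tn <- vapply(spec$tissues, `[[`, character(1), "name")
  tissue <- rep(tn, length.out = n)
  series <- vapply(seq_len(n), function(i) {
    sc <- spec$tissues[[((i - 1) %% length(tn)) + 1]]$series_counts
    names(sc)[((i - 1) %/% length(tn)) %% length(sc) + 1]
  }, character(1))
  list(tissue = tissue, series = series)
}

#' Generate an expression matrix with planted coexpression modules
#'
#' Latent-factor model on the log scale: members of a module share a
#' latent profile f, `log x = mu_p + lambda f + sigma eps`, with lambda
#' calibrated so that `corr = lambda^2 / (lambda^2 + sigma^2)` equals the
#' module's `latent_strength`; background probes are independent noise.
#' Signals are exponentiated around a baseline of ~500 to mimic
#' MAS5-like positive intensity scales (exponentiation shrinks the
#' realized Pearson r slightly below the log-scale target; negligible at
#' the default noise level).
#'
#' @param spec a [fixture_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `modules`
#'   (named list: term -> member probe IDs).
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  np <- spec$n_probes
  ns <- spec$n_samples
  pid <- sprintf("%03d_at", seq_len(np))
  sid <- sprintf("GSM%04d", seq_len(ns))
  mu <- stats::rnorm(np, log(500), 0.2)   # per-probe baseline
  z <- matrix(stats::rnorm(np * ns, sd = spec$noise_sd), np, ns)
  module_map <- list()
  nxt <- 1L
  for (mod in spec$modules) {
    rows <- seq(nxt, nxt + mod$size - 1L)
    nxt <- nxt + mod$size
    lambda <- spec$noise_sd * sqrt(mod$latent_strength /
                                     (1 - mod$latent_strength))
    f <- stats::rnorm(ns)
    z[rows, ] <- z[rows, ] + lambda * rep(f, each = length(rows))
    module_map[[mod$term]] <- pid[rows]
  }
  vals <- exp(mu + z)
  dimnames(vals) <- list(pid, sid)
  meta <- spec_sample_meta(spec, ns)
  list(matrix = expression_matrix(vals, tissue = meta$tissue,
                                  series = meta$series),
       modules = module_map)
}

#' Generate an annotation catalog with planted enriched terms
#'
#' Every member of a planted module is annotated with the module's term
#' in `category`; in addition each probe set carries each of
#' `n_background` background terms independently with probability
#' `background_rate`, plus a unique per-probe `gene_name`.
#'
#' @param spec a [fixture_spec()].
#' @param module_map the `modules` element returned by
#'   [make_expression()].
#' @param category category of the planted terms (default `"go_bp"`,
#'   matched as whole terms).
#' @param background_rate per-probe probability of each background term.
#' @param n_background size of the background term pool.
#' @return an [annotation_catalog()].
#' @export
make_catalog <- function(spec, module_map, category = "go_bp",
                         background_rate = 0.05, n_background = 20) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  pid <- sprintf("%03d_at", seq_len(spec$n_probes))
  rows <- list(data.frame(probe_id = pid, category = "gene_name",
                          term = sprintf("GENE%03d", seq_along(pid)),
                          stringsAsFactors = FALSE))
  for (term in names(module_map)) {
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = module_map[[term]], category = category, term = term,
      stringsAsFactors = FALSE)
  }
  bg <- sprintf("BG%02d", seq_len(n_background))
  hit <- matrix(stats::runif(length(pid) * n_background) < background_rate,
                length(pid), n_background)
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx)) {
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = pid[idx[, 1]], category = category, term = bg[idx[, 2]],
      stringsAsFactors = FALSE)
  }
  annotation_catalog(do.call(rbind, rows))
}

#' Generate raw intensity vectors with planted duplicates
#'
#' Base samples are drawn per tissue/series as specified; then
#' `spec$duplicates` exact copies of existing samples (fresh sample IDs,
#' same tissue/series) are appended, so [deduplicate()] must remove
#' exactly that many.
#'
#' @param spec a [fixture_spec()].
#' @param n_values intensities per sample (stands in for the probe grid
#'   of a real chip).
#' @return list with `samples` (list of [intensity_vector()]) and
#'   `duplicate_ids` (IDs of the planted copies).
#' @export
make_intensity_set <- function(spec, n_values = 64) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  samples <- list()
  k <- 0L
  for (tis in spec$tissues) {
    for (s in names(tis$series_counts)) {
      for (i in seq_len(tis$series_counts[[s]])) {
        k <- k + 1L
        samples[[k]] <- intensity_vector(
          sprintf("GSM%05d", k),
          round(stats::runif(n_values, 0, 65535), 1),
          tissue = tis$name, series = s)
      }
    }
  }
  dup_ids <- character(0)
  if (spec$duplicates > 0) {
    src <- rep(seq_len(k), length.out = spec$duplicates)
    for (i in seq_len(spec$duplicates)) {
      orig <- samples[[src[i]]]
      id <- sprintf("GSM9%04d", i)
      samples[[k + i]] <- intensity_vector(id, orig$values,
                                           tissue = orig$tissue,
                                           series = orig$series)
      dup_ids <- c(dup_ids, id)
    }
  }
  list(samples = samples, duplicate_ids = dup_ids)
}

#' Generate promoter sequences with planted motif sites
#'
#' Sequences of i.i.d. uniform background bases; each promoter
#' independently carries one planted plus-strand consensus site of the
#' PWM (probability `site_rate`) at a uniform random offset, recorded in
#' the ground truth.
#'
#' @param x a [pwm()].
#' @param n number of promoters.
#' @param site_rate per-promoter probability of a planted site.
#' @param seed RNG seed.
#' @param length promoter length in bases (default 500, the upstream
#'   window size).
#' @return list with `sequences` (named character vector) and `sites`
#'   (data.frame `sequence_id`, `offset` 0-based, `strand`).
#' @export
make_promoters <- function(x, n, site_rate, seed, length = 500) {
  stopifnot(inherits(x, "pwm"), n >= 1, site_rate >= 0, site_rate <= 1,
            length >= nrow(x$freq))
  set.seed(seed)
  L <- nrow(x$freq)
  consensus <- paste(DNA_BASES[apply(x$freq, 1, which.max)], collapse = "")
  ids <- sprintf("promoter_%03d", seq_len(n))
  seqs <- character(n)
  sites <- list()
  for (i in seq_len(n)) {
    s <- sample(DNA_BASES, length, replace = TRUE)
    if (stats::runif(1) < site_rate) {
      off <- sample.int(length - L + 1L, 1L) - 1L
      s[(off + 1L):(off + L)] <- strsplit(consensus, "")[[1]]
      sites[[length(sites) + 1L]] <- data.frame(
        sequence_id = ids[i], offset = off, strand = "+",
        stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(sequence_id = character(0), offset = integer(0),
               strand = character(0))
  list(sequences = stats::setNames(seqs, ids), sites = sites)
}
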
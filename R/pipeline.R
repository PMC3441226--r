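# End-to-end pipeline: normalization -> correlation -> tree -> per-query
# ranked lists, neighbourhoods and enrichment, with a run manifest.

#' Pipeline configuration
#'
#' Defaults are the stringency and scaling constants of the method:
#' trimmed-mean target 500 with 2% trim, enrichment cutoff 0.05 on the
#' BH-adjusted p-value, and PWM core/matrix similarity cutoffs
#' 0.95/0.90.
#'
#' @param target,trim trimmed-mean scaling target and trim fraction.
#' @param n_tests Bonferroni family size; `"auto"` = number of unordered
#'   probe pairs.
#' @param rooting,clamp_negative passed to [neighbour_joining()].
#' @param height neighbourhood height for tree queries (correlation
#'   distance units).
#' @param top_k ranked-list length.
#' @param alpha,category enrichment cutoff and annotation category.
#' @param core_cutoff,matrix_cutoff PWM scan thresholds.
#' @param seed RNG seed recorded in the manifest.
#' @return named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(target = 500, trim = 0.02, n_tests = "auto",
                            rooting = "trifurcate", clamp_negative = TRUE,
                            height = 0.5, top_k = 50, alpha = 0.05,
                            category = "go_bp", core_cutoff = 0.95,
                            matrix_cutoff = 0.90, seed = 1) {
  structure(list(target = target, trim = trim, n_tests = n_tests,
                 rooting = rooting, clamp_negative = clamp_negative,
                 height = height, top_k = top_k, alpha = alpha,
                 category = category, core_cutoff = core_cutoff,
                 matrix_cutoff = matrix_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` (or `key value`) pair per line; `#` starts a
#' comment. Keys are the arguments of [pipeline_config()]; unknown keys
#' are an error. Values are coerced to numeric/logical where the default
#' is numeric/logical.
#'
#' @param path file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  defaults <- pipeline_config()
  cfg <- unclass(defaults)
  for (ln in lines) {
    kv <- strsplit(ln, "[=[:space:]]+")[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- kv[1]
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    val <- kv[2]
    cfg[[key]] <- if (is.numeric(defaults[[key]])) {
      as.numeric(val)
    } else if (is.logical(defaults[[key]])) {
      toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else val
  }
  do.call(pipeline_config, cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full upper-triangle pair table with statistics
pair_table <- function(R, n_tests) {
  ids <- rownames(R)
  n <- attr(R, "n_samples")
  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  t <- t_statistic(r, n)
  p <- ifelse(is.infinite(t), 0, p_two_sided(t, n - 2))
  data.frame(probe_x = ids[idx[, 1]], probe_y = ids[idx[, 2]],
             r = r, t = t, p = p, e = bonferroni(p, n_tests),
             stringsAsFactors = FALSE)
}

#' Run the full coexpression pipeline
#'
#' Reads an expression matrix, drops control probe sets, normalizes by
#' per-sample trimmed-mean scaling, computes the all-against-all
#' correlation matrix and pair statistics, converts to distances, builds
#' the Neighbour-Joining tree, and (for each query probe set) writes the
#' r-value-ranked list, the tree neighbourhood at the configured height,
#' and the annotation-term enrichment of that neighbourhood. All outputs
#' plus a JSON run manifest (package version, configuration, output
#' checksums) go to `out_dir`; reruns with the same inputs and
#' configuration are byte-identical.
#'
#' @param matrix_file expression matrix TSV
#'   (see [read_expression_matrix()]).
#' @param out_dir output directory (created if absent).
#' @param queries character vector of driver probe-set IDs (optional).
#' @param annotations_file annotation catalog TSV (optional; enables
#'   enrichment).
#' @param config a [pipeline_config()].
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(matrix_file, out_dir, queries = character(0),
                         annotations_file = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(matrix_file, annotations_file)) {
    if (!file.exists(f)) stop("input not found: ", f, call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  m <- stage("read", read_expression_matrix(matrix_file))
  m <- stage("normalize", {
    if (any(is_control_probeset(probe_ids(m)))) {
      m <- drop_control_probesets(m)
    }
    normalize_matrix(m, trim_fraction = config$trim, target = config$target)
  })
  write_expression_matrix(m, file.path(out_dir, "normalized.tsv"))

  R <- stage("correlate", correlation_matrix(m))
  mprobes <- nrow(R)
  n_tests <- if (identical(config$n_tests, "auto")) {
    mprobes * (mprobes - 1) / 2
  } else config$n_tests
  write_tsv(pair_table(R, n_tests), file.path(out_dir, "pairs.tsv"))

  D <- to_distance(R)
  write_phylip_distances(D, file.path(out_dir, "distances.phy"))
  tree <- stage("tree", neighbour_joining(
    D, clamp_negative = config$clamp_negative, rooting = config$rooting))
  write_newick(tree, file.path(out_dir, "tree.nwk"))

  catalog <- if (!is.null(annotations_file)) {
    stage("annotations", read_annotation_catalog(annotations_file))
  }
  for (q in queries) {
    stage(paste0("query:", q), {
      write_tsv(ranked_list(q, R, k = config$top_k, n_tests = n_tests),
                file.path(out_dir, paste0("ranked_", q, ".tsv")))
      nb <- tree_ranked_list(tree, q, config$height, R)
      write_tsv(nb, file.path(out_dir, paste0("neighborhood_", q, ".tsv")))
      if (!is.null(catalog)) {
        members <- intersect(nb$probe_id,
                             unique(catalog$entries$probe_id))
        if (length(members)) {
          write_tsv(enrich(members, catalog, config$category,
                           alpha = config$alpha),
                    file.path(out_dir,
                              paste0("enrichment_", q, "_",
                                     config$category, ".tsv")))
        }
      }
    })
  }

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "coextree",
    version = as.character(utils::packageVersion("coextree")),
    config = unclass(config),
    inputs = list(matrix = matrix_file,
                  annotations = annotations_file),
    queries = queries,
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
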
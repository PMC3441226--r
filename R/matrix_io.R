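# IO for every external representation the pipeline touches:
# expression matrices (TSV), annotation catalogs (TSV), Phylip distance
# matrices (relaxed dialect), Newick trees, and PWM files (see pwm_scan.R).

#' Construct an expression matrix
#'
#' Container for probe-set x sample signal values plus per-sample metadata
#' (tissue/organ and sample-series labels, used by [balanced_selection()]
#' and carried along by the pipeline).
#'
#' @param values numeric matrix, rows = probe sets (rownames are probe-set
#'   IDs), columns = samples (colnames are sample IDs). All values must be
#'   finite and non-negative.
#' @param tissue,series optional character vectors (one per sample);
#'   default empty strings.
#' @return an object of class `"expr_matrix"`: a list with elements
#'   `values` (the matrix) and `sample_meta` (data.frame with columns
#'   `sample_id`, `tissue`, `series`).
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("a_at", "b_at"), c("S1", "S2", "S3"))))
#' @export
expression_matrix <- function(values, tissue = NULL, series = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid)) {
    stop("'values' must have probe-set rownames and sample colnames",
         call. = FALSE)
  }
  validate_probe_ids(pid)
  if (anyDuplicated(pid)) {
    stop("duplicate probe-set ID: ", pid[duplicated(pid)][1], call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ID: ", sid[duplicated(sid)][1], call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  n <- length(sid)
  if (is.null(tissue)) tissue <- rep("", n)
  if (is.null(series)) series <- rep("", n)
  stopifnot(length(tissue) == n, length(series) == n)
  structure(
    list(values = values,
         sample_meta = data.frame(sample_id = sid,
                                  tissue = as.character(tissue),
                                  series = as.character(series),
                                  stringsAsFactors = FALSE)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probe sets x %d samples\n",
              nrow(x$values), ncol(x$values)))
  nt <- length(unique(x$sample_meta$tissue[nzchar(x$sample_meta$tissue)]))
  if (nt > 0) cat(sprintf("  tissues: %d\n", nt))
  invisible(x)
}

#' Probe-set and sample accessors
#' @param m an `expr_matrix`.
#' @return character vector of IDs.
#' @export
probe_ids <- function(m) rownames(m$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read an expression matrix from tab-separated text
#'
#' File layout: first row is `probe_set_id` followed by sample IDs; an
#' optional row starting with `#tissue` carries tissue labels and an
#' optional row starting with `#series` carries series labels; every other
#' row is a probe-set ID followed by one signal value per sample. Missing
#' metadata rows yield empty tissue/series strings.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop("expression file has no data rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) {
    stop("header row must contain at least one sample ID", call. = FALSE)
  }
  sid <- header[-1]
  ns <- length(sid)
  tissue <- rep("", ns)
  series <- rep("", ns)
  i <- 2
  while (i <= length(fields) && fields[[i]][1] %in% c("#tissue", "#series")) {
    row <- fields[[i]]
    if (length(row) != ns + 1) {
      stop(sprintf("row %d (%s): expected %d fields, found %d",
                   i, row[1], ns + 1, length(row)), call. = FALSE)
    }
    if (row[1] == "#tissue") tissue <- row[-1] else series <- row[-1]
    i <- i + 1
  }
  data_rows <- fields[seq(i, length(fields))]
  pid <- vapply(data_rows, `[`, character(1), 1)
  vals <- matrix(NA_real_, length(pid), ns,
                 dimnames = list(pid, sid))
  for (j in seq_along(data_rows)) {
    row <- data_rows[[j]]
    if (length(row) != ns + 1) {
      stop(sprintf("row %d (%s): expected %d fields, found %d",
                   i + j - 1, row[1], ns + 1, length(row)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("row %d (%s), column %d: non-numeric value '%s'",
                   i + j - 1, row[1], bad, row[bad + 1]), call. = FALSE)
    }
    vals[j, ] <- v
  }
  if (anyDuplicated(pid)) {
    stop("duplicate probe-set row ID: ", pid[duplicated(pid)][1],
         call. = FALSE)
  }
  expression_matrix(vals, tissue = tissue, series = series)
}

#' Write an expression matrix as tab-separated text
#'
#' @param m an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_set_id", sample_ids(m)), collapse = "\t"), con)
  meta <- m$sample_meta
  if (any(nzchar(meta$tissue))) {
    writeLines(paste(c("#tissue", meta$tissue), collapse = "\t"), con)
  }
  if (any(nzchar(meta$series))) {
    writeLines(paste(c("#series", meta$series), collapse = "\t"), con)
  }
  body <- apply(m$values, 1, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE,
                 drop0trailing = TRUE), collapse = "\t"))
  writeLines(paste(probe_ids(m), body, sep = "\t"), con)
  invisible(path)
}

#' Construct an annotation catalog
#'
#' Maps probe sets to annotation terms within a fixed category vocabulary
#' (gene_name, description, go_bp, go_cc, go_mf, ec, omim, pathway,
#' interpro, transfac). Probe sets absent from the catalog are treated as
#' having empty term sets in every category.
#'
#' @param entries data.frame with character columns `probe_id`, `category`,
#'   `term`; one row per (probe set, category, term) triple.
#' @return an object of class `"annotation_catalog"`.
#' @export
annotation_catalog <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("probe_id", "category", "term") %in% names(entries)))
  entries <- entries[, c("probe_id", "category", "term")]
  entries[] <- lapply(entries, as.character)
  validate_probe_ids(unique(entries$probe_id))
  bad <- setdiff(unique(entries$category), ANNOTATION_CATEGORIES)
  if (length(bad)) {
    stop("unknown annotation categor(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  entries <- unique(entries[nzchar(entries$term), ])
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog: %d probe sets, %d entries, %d categories\n",
              length(unique(x$entries$probe_id)), nrow(x$entries),
              length(unique(x$entries$category))))
  invisible(x)
}

#' Read / write annotation catalogs
#'
#' Tab-separated layout: `probe_id<TAB>category<TAB>term1|term2|...`, one
#' line per probe set and category.
#'
#' @param path file path.
#' @return [read_annotation_catalog()] returns an [annotation_catalog()];
#'   the writer returns `path` invisibly.
#' @export
read_annotation_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                          col.names = c("probe_id", "category", "terms"),
                          colClasses = "character", comment.char = "")
  terms <- strsplit(df$terms, "|", fixed = TRUE)
  n <- lengths(terms)
  annotation_catalog(data.frame(
    probe_id = rep(df$probe_id, n),
    category = rep(df$category, n),
    term = unlist(terms),
    stringsAsFactors = FALSE))
}

#' @rdname read_annotation_catalog
#' @param catalog an `annotation_catalog`.
#' @export
write_annotation_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  e <- catalog$entries
  key <- paste(e$probe_id, e$category, sep = "\r")
  terms <- vapply(split(e$term, key), function(x)
    paste(sort(x), collapse = "|"), character(1))
  parts <- strsplit(names(terms), "\r", fixed = TRUE)
  out <- data.frame(probe_id = vapply(parts, `[`, character(1), 1),
                    category = vapply(parts, `[`, character(1), 2),
                    terms = unname(terms))
  out <- out[order(out$probe_id, out$category), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(D))) {
    stop("distance matrix must have leaf names as rownames", call. = FALSE)
  }
  if (any(abs(diag(D)) > tol)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (max(abs(D - t(D))) > tol) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  invisible(D)
}

#' Write a distance matrix in (relaxed) Phylip format
#'
#' First line is the leaf count; each following line is a leaf name, a
#' space, then the full-precision distances to every leaf. Classic Phylip
#' truncates names at 10 characters, which mangles 11-character Affymetrix
#' probe-set IDs such as `200725_x_at`; the default relaxed dialect keeps
#' full whitespace-free names. `strict = TRUE` truncates to 10 characters
#' for interoperability with classic Phylip tools.
#'
#' @param D symmetric numeric matrix, zero diagonal, leaf names as
#'   rownames (no internal whitespace).
#' @param path output file path.
#' @param strict truncate names to 10 characters (classic Phylip)?
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(D, path, strict = FALSE) {
  validate_distance_matrix(D)
  nm <- rownames(D)
  if (any(grepl("\\s", nm))) {
    stop("leaf names must not contain whitespace: ",
         nm[grepl("\\s", nm)][1], call. = FALSE)
  }
  if (strict) {
    nm <- substr(nm, 1, 10)
    if (anyDuplicated(nm)) {
      stop("strict-mode truncation makes leaf names collide", call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(nm[i], paste(sprintf("%.17g", D[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a (relaxed) Phylip distance matrix
#'
#' @param path file path written by [write_phylip_distances()] or any
#'   whitespace-delimited square Phylip distance file with one leaf per
#'   line.
#' @return symmetric numeric matrix with leaf names as dimnames.
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("first line must be the leaf count", call. = FALSE)
  }
  if (length(lines) != n + 1) {
    stop(sprintf("expected %d leaf lines, found %d", n, length(lines) - 1),
         call. = FALSE)
  }
  D <- matrix(NA_real_, n, n)
  nm <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(tok) != n + 1) {
      stop(sprintf("leaf line %d: expected %d distances, found %d",
                   i, n, length(tok) - 1), call. = FALSE)
    }
    nm[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(v)) {
      stop(sprintf("leaf line %d: non-numeric distance", i), call. = FALSE)
    }
    D[i, ] <- v
  }
  dimnames(D) <- list(nm, nm)
  validate_distance_matrix(D)
  D
}

#' Write / read Newick trees
#'
#' Standard Newick with branch lengths, terminated by `";"`. Branch
#' lengths are written with 9 significant digits; unlabeled internal nodes
#' are allowed. `read_newick` validates parenthesis balance and the
#' terminating semicolon before parsing, reporting the character offset of
#' the first structural error.
#'
#' @param tree an [ape::phylo] object with unique leaf labels.
#' @param path file path.
#' @param digits significant digits for branch lengths.
#' @return the writer returns `path` invisibly; the reader returns a
#'   `phylo` tree.
#' @export
write_newick <- function(tree, path, digits = 9) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("leaf labels must be unique", call. = FALSE)
  }
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error at character ", i,
             ": unmatched ')'", call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error at character ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  }
  if (!grepl(";\\s*$", txt)) {
    stop("Newick parse error at character ", nchar(txt),
         ": missing terminating ';'", call. = FALSE)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  tree
}
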
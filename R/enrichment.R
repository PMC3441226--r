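# Annotation-term over-representation for a coexpression list:
# tokenization of free-text annotations, hypergeometric upper-tail p,
# Benjamini-Hochberg correction, significance trimming.

STOP_WORDS <- c(
  "THE", "AND", "FOR", "WITH", "FROM", "THAT", "THIS", "ARE", "WAS", "NOT",
  "ITS", "VIA", "PER", "HAS", "HAVE", "INTO", "ALSO", "MAY", "BUT", "ALL",
  "LIKE", "TYPE", "NON", "PUTATIVE", "HYPOTHETICAL")

#' Tokenize free-text annotation into terms
#'
#' Uppercases the text and splits it on non-alphanumeric boundaries;
#' tokens shorter than 3 characters, bare numerals, and a small fixed
#' English stop-word list are removed. Used for the gene-name and
#' gene-description categories only: structured annotations (GO IDs,
#' pathways, EC, OMIM, InterPro, TransFac) are matched as whole terms.
#'
#' @param text character vector of free-text annotations.
#' @return character vector of unique uppercase tokens (a term set).
#' @examples
#' tokenize("ribosomal protein L10")  # RIBOSOMAL PROTEIN L10
#' tokenize("testis expressed 14")    # TESTIS EXPRESSED
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(character(0))
  tok <- unlist(strsplit(toupper(text), "[^A-Z0-9]+"))
  tok <- tok[nchar(tok) >= 3]
  tok <- tok[!grepl("^[0-9]+$", tok)]
  unique(tok[!tok %in% STOP_WORDS])
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(population `n`, `m` successes,
#' `c` draws): the probability of observing at least `k` annotated probe
#' sets in a list of `c` drawn from a universe of `n` containing `m`
#' probe sets with the term. Computed as a log-space sum of
#' `C(m, i) C(n - m, c - i) / C(n, c)` for numerical stability.
#'
#' @param n universe size (total probe sets).
#' @param m probe sets in the universe carrying the term.
#' @param c list size.
#' @param k probe sets in the list carrying the term.
#' @return probability in \[0, 1\]; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper(10, 5, 5, 5)  # 1/252
#' @export
hypergeom_upper <- function(n, m, c, k) {
  stopifnot(length(n) == 1, length(m) == 1, length(c) == 1, length(k) == 1)
  if (m > n || c > n || k < 0 || k > min(c, m)) {
    stop(sprintf(
      "invalid hypergeometric parameters: n=%d m=%d c=%d k=%d", n, m, c, k),
      call. = FALSE)
  }
  if (k == 0) return(1)
  i <- k:min(c, m)
  lp <- lchoose(m, i) + lchoose(n - m, c - i) - lchoose(n, c)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure: with the M p-values sorted ascending,
#' `adj_i = min_{j >= i} (M p_j / j)`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  M <- length(p)
  if (M == 0) return(numeric(0))
  ord <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[ord] * M / seq_len(M)))))
  out <- numeric(M)
  out[ord] <- adj_sorted
  out
}

# term sets per probe for one category; free-text categories tokenized
probe_term_sets <- function(catalog, category) {
  e <- catalog$entries[catalog$entries$category == category, ]
  sets <- split(e$term, e$probe_id)
  if (category %in% c("gene_name", "description")) {
    sets <- lapply(sets, tokenize)
  } else {
    sets <- lapply(sets, unique)
  }
  sets[lengths(sets) > 0]
}

#' Term over-representation in a coexpression list
#'
#' For every term annotated (in the chosen category) to at least one
#' probe set of the list, tests whether the term occurs more often in the
#' list than expected under the hypergeometric null given its frequency
#' in the universe. The universe is the set of probe sets present in the
#' catalog. Raw p-values are [hypergeom_upper()] upper tails; adjusted
#' p-values are [bh_adjust()]ed over all terms tested in the category,
#' and records with `p_adj <= alpha` are returned, ascending `p_adj`
#' (ties by term).
#'
#' @param probe_list character vector of probe-set IDs (the coexpression
#'   neighbourhood of a driver probe set).
#' @param catalog an [annotation_catalog()].
#' @param category one of the catalog categories; `gene_name` and
#'   `description` entries are tokenized, all others matched as whole
#'   terms.
#' @param alpha significance cutoff on the BH-adjusted p-value
#'   (default 0.05); `alpha = 1` returns every tested term.
#' @return data.frame with columns `term`, `category`, `n`, `m`, `c`,
#'   `k`, `p_raw`, `p_adj`.
#' @export
enrich <- function(probe_list, catalog, category, alpha = 0.05) {
  stopifnot(inherits(catalog, "annotation_catalog"),
            length(probe_list) > 0, alpha >= 0, alpha <= 1)
  category <- match.arg(category, ANNOTATION_CATEGORIES)
  universe <- unique(catalog$entries$probe_id)
  if (length(universe) == 0) {
    stop("annotation catalog is empty", call. = FALSE)
  }
  probe_list <- unique(probe_list)
  outside <- setdiff(probe_list, universe)
  if (length(outside)) {
    stop("probe set(s) not in the catalog universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  sets <- probe_term_sets(catalog, category)
  n <- length(universe)
  c_ <- length(probe_list)
  # term -> count in universe (m) and in list (k)
  all_terms <- unlist(sets, use.names = FALSE)
  m_count <- table(all_terms)
  in_list <- unlist(sets[names(sets) %in% probe_list], use.names = FALSE)
  k_count <- table(in_list)
  terms <- sort(names(k_count))
  if (length(terms) == 0) {
    return(data.frame(term = character(0), category = character(0),
                      n = integer(0), m = integer(0), c = integer(0),
                      k = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  }
  m_v <- as.integer(m_count[terms])
  k_v <- as.integer(k_count[terms])
  p_raw <- vapply(seq_along(terms), function(i)
    hypergeom_upper(n, m_v[i], c_, k_v[i]), numeric(1))
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(term = terms, category = category, n = n, m = m_v,
                    c = c_, k = k_v, p_raw = p_raw, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out <- out[out$p_adj <= alpha, ]
  out <- out[order(out$p_adj, out$term), ]
  rownames(out) <- NULL
  out
}
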
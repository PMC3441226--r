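# Correlation -> distance conversion, canonical Saitou-Nei Neighbour
# Joining, and height-adjustable tree neighbourhoods around a driver
# probe set.

#' Convert a correlation matrix to a distance matrix
#'
#' `D(x, y) = 1 - R(x, y)` elementwise: perfectly correlated probe sets
#' are at distance 0, perfectly anti-correlated at distance 2.
#'
#' @param R symmetric correlation matrix (unit diagonal, probe IDs as
#'   dimnames), e.g. from [correlation_matrix()].
#' @return symmetric distance matrix with zero diagonal, entries in
#'   \[0, 2\].
#' @export
to_distance <- function(R) {
  stopifnot(is.matrix(R), is.numeric(R))
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8)) {
    stop("'R' must be symmetric with unit diagonal", call. = FALSE)
  }
  D <- 1 - R
  diag(D) <- 0
  attr(D, "n_samples") <- attr(R, "n_samples")
  D
}

# Convert the nested-list tree built by NJ into an ape "phylo" object.
# Preorder traversal: internal nodes numbered before their children's
# subtrees, edges recorded in cladewise order.
nj_to_phylo <- function(root) {
  count_tips <- function(nd) {
    if (is.null(nd$children)) 1L
    else sum(vapply(nd$children, count_tips, integer(1)))
  }
  ntip <- count_tips(root)
  env <- new.env(parent = emptyenv())
  env$tip <- 0L
  env$node <- ntip
  env$labels <- character(ntip)
  env$parent <- integer(0)
  env$child <- integer(0)
  env$len <- numeric(0)
  rec <- function(nd) {
    if (is.null(nd$children)) {
      env$tip <- env$tip + 1L
      env$labels[env$tip] <- nd$label
      return(env$tip)
    }
    env$node <- env$node + 1L
    my <- env$node
    for (i in seq_along(nd$children)) {
      slot <- length(env$parent) + 1L
      env$parent[slot] <- my
      env$child[slot] <- NA_integer_
      env$len[slot] <- nd$blen[i]
      env$child[slot] <- rec(nd$children[[i]])
    }
    my
  }
  rec(root)
  structure(list(edge = cbind(env$parent, env$child, deparse.level = 0),
                 edge.length = env$len,
                 tip.label = env$labels,
                 Nnode = env$node - ntip),
            class = "phylo", order = "cladewise")
}

#' Neighbour-Joining coexpression tree
#'
#' Canonical Saitou-Nei NJ: iteratively join the pair (i, j) minimizing
#' `Q(i, j) = (N - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with
#' branch lengths from the standard two-point formulas and distances to
#' the new node `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. The last
#' three nodes are joined at a trifurcating root (NJ is inherently
#' unrooted); `rooting = "midpoint"` midpoint-roots the result instead.
#' Q-ties are broken by the lowest (i, j) index pair in canonical input
#' order, so the output is fully deterministic. Negative branch lengths
#' (possible for non-additive input) are clamped to 0 with the deficit
#' moved to the sister edge, preserving path lengths through the join.
#'
#' @param D symmetric distance matrix with zero diagonal and leaf names
#'   as rownames (>= 2 leaves), e.g. from [to_distance()].
#' @param clamp_negative clamp negative branch lengths (default TRUE)?
#' @param rooting `"trifurcate"` (default) or `"midpoint"`.
#' @return an [ape::phylo] tree whose tips are exactly the input leaves.
#' @export
neighbour_joining <- function(D, clamp_negative = TRUE,
                              rooting = c("trifurcate", "midpoint")) {
  rooting <- match.arg(rooting)
  validate_distance_matrix(D)
  labels <- rownames(D)
  n0 <- length(labels)
  if (n0 < 2) stop("need at least 2 leaves", call. = FALSE)
  nodes <- lapply(labels, function(l) list(label = l))
  d <- unname(D)
  clamped <- 0L
  clamp2 <- function(b) {
    # move any deficit to the sister edge so the i--j path keeps length d(i,j)
    if (b[1] < 0) { b[2] <- b[2] + b[1]; b[1] <- 0; clamped <<- clamped + 1L }
    if (b[2] < 0) { b[1] <- b[1] + b[2]; b[2] <- 0; clamped <<- clamped + 1L }
    pmax(b, 0)
  }
  while (length(nodes) > 3) {
    N <- length(nodes)
    rs <- rowSums(d)
    Q <- (N - 2) * d - outer(rs, rs, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    bi <- 0.5 * d[i, j] + (rs[i] - rs[j]) / (2 * (N - 2))
    b <- c(bi, d[i, j] - bi)
    if (clamp_negative) b <- clamp2(b)
    newnode <- list(children = list(nodes[[i]], nodes[[j]]), blen = b)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
  }
  if (length(nodes) == 2) {
    root <- list(children = nodes, blen = c(d[1, 2] / 2, d[1, 2] / 2))
  } else {
    b <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    if (clamp_negative && any(b < 0)) {
      clamped <- clamped + sum(b < 0)
      b <- pmax(b, 0)
    }
    root <- list(children = nodes, blen = b)
  }
  tr <- nj_to_phylo(root)
  if (clamped > 0L) {
    message("neighbour_joining: clamped ", clamped,
            " negative branch length(s)")
  }
  if (rooting == "midpoint") {
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("midpoint rooting requires the 'phangorn' package", call. = FALSE)
    }
    tr <- phangorn::midpoint(tr)
  }
  tr
}

# parent lookup: parent[k] is the parent node of node k (0 for the root);
# plen[k] is the length of the edge above node k.
tree_parents <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(nn)
  plen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  list(parent = parent, plen = plen)
}

# all tip labels in the clade under 'node'
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- c(tips, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  tree$tip.label[sort(tips)]
}

#' Height-adjustable tree neighbourhood of a driver probe set
#'
#' Ascends the tree from the query leaf through its ancestors while the
#' path length from the leaf to the ancestor is at most `h`, then returns
#' all leaves of the clade under the deepest such ancestor. Enlarging `h`
#' enlarges (never shrinks) the neighbourhood; `h = 0` returns only the
#' query itself.
#'
#' @param tree a `phylo` tree from [neighbour_joining()].
#' @param q query probe-set ID (a tip label of `tree`).
#' @param h neighbourhood height: maximum path length (in correlation
#'   distance units) from the query leaf to the clade ancestor (>= 0).
#' @return list of class `"coex_neighborhood"` with `query`, `height`,
#'   `members` (character vector including `q`).
#' @export
neighborhood <- function(tree, q, h) {
  stopifnot(inherits(tree, "phylo"), is.numeric(h), length(h) == 1, h >= 0)
  tip <- match(q, tree$tip.label)
  if (is.na(tip)) stop("query probe set not in tree: ", q, call. = FALSE)
  pm <- tree_parents(tree)
  node <- tip
  best <- tip
  depth <- 0
  repeat {
    p <- pm$parent[node]
    if (p == 0L) break
    depth <- depth + pm$plen[node]
    if (depth <= h) {
      best <- p
      node <- p
    } else break
  }
  structure(list(query = q, height = h, members = clade_tips(tree, best)),
            class = "coex_neighborhood")
}

#' @export
print.coex_neighborhood <- function(x, ...) {
  cat(sprintf("neighborhood of %s at height %g: %d probe set(s)\n",
              x$query, x$height, length(x$members)))
  invisible(x)
}

#' r-value-ranked list of a tree neighbourhood
#'
#' The members of the [neighborhood()] of `q`, ordered by descending
#' correlation with `q` (the query first, ties by probe-set ID) — the
#' tree-based counterpart of [ranked_list()].
#'
#' @inheritParams neighborhood
#' @param R correlation matrix covering the tree's tips.
#' @return data.frame with columns `probe_id` and `r`.
#' @export
tree_ranked_list <- function(tree, q, h, R) {
  nb <- neighborhood(tree, q, h)
  others <- setdiff(nb$members, q)
  if (length(others)) {
    r <- R[q, others]
    ord <- order(-r, others)
    df <- data.frame(probe_id = c(q, others[ord]),
                     r = c(1, unname(r[ord])),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(probe_id = q, r = 1, stringsAsFactors = FALSE)
  }
  df
}
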
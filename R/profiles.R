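#' Hierarchical clustering of cells with multiscale bootstrap support
#'
#' Cells are clustered on `1 - Pearson correlation` of their TF profiles
#' with average linkage. Node support is a multiscale bootstrap
#' proportion: the TF rows are resampled with replacement at each
#' relative sample-size fraction of the grid, the tree rebuilt, and a
#' node's support is the percentage of replicate trees containing its
#' exact leaf set. Per-fraction proportions are retained; the headline
#' support is their mean over the grid. These are plain bootstrap
#' proportions (BP), not selective-inference corrected values.
#'
#' @param matrix an `expression_matrix` (TF rows x cell columns).
#' @param n_boot bootstrap replicates per fraction (default 1000).
#' @param frac_grid relative sample-size grid (default 0.5 to 1.4 by 0.1).
#' @return A `cell_dendrogram`: list with `hclust`, `support` (percent per
#'   internal node), `bp_table` (node x fraction proportions), `leafsets`,
#'   and `dropped` (constant-profile cells removed).
#' @export
cluster_cells <- function(matrix, n_boot = 1000L,
                          frac_grid = seq(0.5, 1.4, by = 0.1)) {
  m <- unclass(as.matrix(matrix))
  if (ncol(m) < 3L) stop("need at least 3 cells to cluster")
  v <- apply(m, 2L, stats::var)
  dropped <- colnames(m)[v <= 0]
  if (length(dropped)) {
    warning("dropping constant-profile cells: ",
            paste(dropped, collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  hc <- hclust(stats::as.dist(1 - cor(m)), method = "average")
  leafsets <- node_leafsets(hc)
  keys <- vapply(leafsets, function(s) paste(sort(s), collapse = "\r"),
                 character(1L))
  ntf <- nrow(m)
  bp <- matrix(0, length(keys), length(frac_grid),
               dimnames = list(NULL, sprintf("%.1f", frac_grid)))
  for (fi in seq_along(frac_grid)) {
    size <- max(2L, round(frac_grid[fi] * ntf))
    hits <- numeric(length(keys))
    for (b in seq_len(n_boot)) {
      mb <- m[sample.int(ntf, size, replace = TRUE), , drop = FALSE]
      cors <- suppressWarnings(cor(mb))
      cors[!is.finite(cors)] <- 0
      hb <- hclust(stats::as.dist(1 - cors), method = "average")
      kb <- vapply(node_leafsets(hb),
                   function(s) paste(sort(s), collapse = "\r"),
                   character(1L))
      hits <- hits + (keys %in% kb)
    }
    bp[, fi] <- hits / n_boot
  }
  structure(list(hclust = hc,
                 support = 100 * rowMeans(bp),
                 bp_table = bp,
                 leafsets = leafsets,
                 dropped = dropped),
            class = "cell_dendrogram")
}

#' @export
print.cell_dendrogram <- function(x, ...) {
  cat(sprintf("<cell_dendrogram> %d cells, %d internal nodes (BP support: mean %.1f%%)\n",
              length(x$hclust$labels), length(x$support), mean(x$support)))
  invisible(x)
}

# leaf-label sets of each internal node of an hclust tree (merge order)
node_leafsets <- function(hc) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- hc$merge[i, ]
    sets[[i]] <- c(
      if (kids[1L] < 0) hc$labels[-kids[1L]] else sets[[kids[1L]]],
      if (kids[2L] < 0) hc$labels[-kids[2L]] else sets[[kids[2L]]])
  }
  sets
}

# rooted binary tree structure from an hclust object:
# nodes 1..n are leaves, n+1..2n-1 internal (merge i -> node n+i)
tree_structure <- function(hc) {
  n <- length(hc$labels)
  parent <- integer(2L * n - 1L)
  children <- matrix(0L, n - 1L, 2L)
  for (i in seq_len(n - 1L)) {
    kids <- ifelse(hc$merge[i, ] < 0, -hc$merge[i, ], hc$merge[i, ] + n)
    children[i, ] <- kids
    parent[kids] <- n + i
  }
  list(n_leaves = n, root = 2L * n - 1L, parent = parent,
       children = children, labels = hc$labels)
}

#' Parsimony subtyping of a cell type on the expression dendrogram
#'
#' Leaves are two-state (given type vs other); internal nodes are
#' labelled by small-parsimony minimization of the number of bichromatic
#' (inter-type) edges. Fitch-style ties are resolved top-down by
#' inheriting the parent's state, with root ties resolving to "other"
#' (conservative: fewer, tighter subtypes). Subtypes are the connected
#' components of given-type nodes that contain given-type leaves. Each
#' subtype's neighbor clade is the maximal clade free of given-type
#' cells that is reachable through the fewest inter-type edges; since
#' edges between other-type nodes cost nothing under this metric, ties
#' are broken by path length (nearest clade in the tree), then towards
#' the larger clade, then traversal order.
#'
#' @param tree a `cell_dendrogram` or `hclust` over cells.
#' @param given_cells character vector: leaves of the queried cell type.
#' @return A `subtype_result`: list with `subtypes` (list of cell-id
#'   sets), `neighbors` (matching list of neighbor-clade cell sets),
#'   `inter_type_edges` (the minimized count), and `node_states`.
#' @export
subtype_by_parsimony <- function(tree, given_cells) {
  hc <- if (inherits(tree, "cell_dendrogram")) tree$hclust else tree
  ts <- tree_structure(hc)
  n <- ts$n_leaves
  nn <- 2L * n - 1L
  if (!length(intersect(given_cells, ts$labels)))
    stop("no given-type leaf present in the tree")
  leaf_state <- as.integer(ts$labels %in% given_cells)  # 1 = given
  # bottom-up DP over states {0, 1}; edge cost 1 when states differ
  cost <- matrix(Inf, nn, 2L)
  cost[seq_len(n), ] <- cbind(ifelse(leaf_state == 0L, 0, Inf),
                              ifelse(leaf_state == 1L, 0, Inf))
  for (i in seq_len(n - 1L)) {
    v <- n + i
    for (s in 0:1) {
      tot <- 0
      for (c in ts$children[i, ])
        tot <- tot + min(cost[c, 1L] + (s != 0L), cost[c, 2L] + (s != 1L))
      cost[v, s + 1L] <- tot
    }
  }
  state <- integer(nn)
  state[seq_len(n)] <- leaf_state
  root <- ts$root
  state[root] <- if (cost[root, 1L] <= cost[root, 2L]) 0L else 1L
  for (i in rev(seq_len(n - 1L))) {       # parents precede children downwards
    v <- n + i
    for (c in ts$children[i, ]) {
      if (c <= n) next
      c0 <- cost[c, 1L] + (state[v] != 0L)
      c1 <- cost[c, 2L] + (state[v] != 1L)
      state[c] <- if (c0 < c1) 0L else if (c1 < c0) 1L else state[v]
    }
  }
  edges <- cbind(ts$parent[-root], seq_len(nn)[-root])
  inter <- state[edges[, 1L]] != state[edges[, 2L]]
  # connected components over monochromatic edges
  comp <- seq_len(nn)
  find <- function(a) { while (comp[a] != a) { comp[a] <<- comp[comp[a]]; a <- comp[a] }; a }
  for (e in which(!inter)) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) comp[a] <- b
  }
  comp_id <- vapply(seq_len(nn), find, integer(1L))
  given_comps <- unique(comp_id[seq_len(n)][leaf_state == 1L])

  # per-node leaf sets; a node is "pure other" when no given leaf sits
  # below it, and candidate neighbor clades are the maximal such nodes
  below <- vector("list", nn)
  below[seq_len(n)] <- as.list(ts$labels)
  for (i in seq_len(n - 1L))
    below[[n + i]] <- c(below[[ts$children[i, 1L]]],
                        below[[ts$children[i, 2L]]])
  pure <- vapply(below, function(lv) !any(lv %in% given_cells), logical(1L))
  maximal <- which(pure & (ts$parent == 0L | !pure[pmax(ts$parent, 1L)]))

  adj <- vector("list", nn)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, inter[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, inter[e]))
  }
  sub_list <- list(); nb_list <- list()
  for (g in given_comps) {
    members <- which(comp_id == g)
    sub_cells <- ts$labels[intersect(members, seq_len(n))]
    # multi-source BFS over the tree recording (inter-type edges, length)
    d_int <- rep(Inf, nn); d_len <- rep(Inf, nn)
    d_int[members] <- 0; d_len[members] <- 0
    queue <- members
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1L]; w <- adj[[v]][r, 2L]
        ni <- d_int[v] + w; nl <- d_len[v] + 1
        if (ni < d_int[u] || (ni == d_int[u] && nl < d_len[u])) {
          d_int[u] <- ni; d_len[u] <- nl
          queue <- c(queue, u)
        }
      }
    }
    nb_cells <- character(0L)
    if (length(maximal)) {
      sizes <- vapply(maximal, function(v) length(below[[v]]), integer(1L))
      ord <- order(d_int[maximal], d_len[maximal], -sizes, maximal)
      nb_cells <- below[[maximal[ord[1L]]]]
    }
    sub_list[[length(sub_list) + 1L]] <- sub_cells
    nb_list[[length(nb_list) + 1L]] <- nb_cells
  }
  structure(list(subtypes = sub_list, neighbors = nb_list,
                 inter_type_edges = sum(inter),
                 node_states = state),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("<subtype_result> %d subtypes, %d inter-type edges\n",
              length(x$subtypes), x$inter_type_edges))
  for (i in seq_along(x$subtypes))
    cat(sprintf("  subtype %d: %d cells (neighbor clade: %d cells)\n",
                i, length(x$subtypes[[i]]), length(x$neighbors[[i]])))
  invisible(x)
}

# TF-profile column -> probability distribution (uniform for all-zero cells)
profile_to_prob <- function(v) {
  v <- pmax(v, 0)
  s <- sum(v)
  if (s <= 0) rep(1 / length(v), length(v)) else v / s
}

# Jensen-Shannon divergence, base-2 logs, in [0, 1]
jsd_pair <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) { i <- a > 0; sum(a[i] * log2(a[i] / m[i])) }
  (kl(p) + kl(q)) / 2
}

#' Mean Jensen-Shannon divergence between two cell groups
#'
#' Each cell's TF profile is normalized to a probability distribution
#' (all-zero cells map to the uniform distribution); the group score is
#' the mean base-2 JSD over all cross-group cell pairs, bounded in
#' \[0, 1\].
#'
#' @param matrix an `expression_matrix` (TF rows x cell columns).
#' @param groupA,groupB disjoint, non-empty sets of cell identities.
#' @return Mean JSD in \[0, 1\].
#' @export
group_jsd <- function(matrix, groupA, groupB) {
  m <- unclass(as.matrix(matrix))
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  miss <- setdiff(c(groupA, groupB), colnames(m))
  if (length(miss)) stop("cells absent from matrix: ",
                         paste(miss, collapse = ", "))
  pa <- lapply(groupA, function(c) profile_to_prob(m[, c]))
  pb <- lapply(groupB, function(c) profile_to_prob(m[, c]))
  mean(vapply(pa, function(p)
    mean(vapply(pb, function(q) jsd_pair(p, q), numeric(1L))), numeric(1L)))
}

#' Normalized inter-subtype JSD
#'
#' The JSD between two subtypes divided by the mean of their
#' cross-neighbor-clade JSDs, `JSD(s1, s2) / mean(JSD(s1, n2),
#' JSD(s2, n1))`. Values well below 1 indicate the subtypes are closer to
#' each other than to their respective molecular neighborhoods.
#'
#' @param matrix an `expression_matrix`.
#' @param s1,s2 the two subtypes (disjoint cell sets).
#' @param n1,n2 their neighbor clades (disjoint from each other and from
#'   the subtypes).
#' @return The normalized score; error if the denominator is degenerate.
#' @export
normalized_subtype_jsd <- function(matrix, s1, s2, n1, n2) {
  groups <- list(s1, s2, n1, n2)
  for (i in seq_along(groups)) for (j in seq_len(i - 1L))
    if (length(intersect(groups[[i]], groups[[j]])))
      stop("the four cell sets must be pairwise disjoint")
  num <- group_jsd(matrix, s1, s2)
  den <- mean(c(group_jsd(matrix, s1, n2), group_jsd(matrix, s2, n1)))
  if (den < 1e-12)
    stop("undefined result: cross-neighbor-clade JSDs are degenerate (~0)")
  num / den
}

#' Exact two-sided Fisher test for a 2 x 2 table
#'
#' Direct hypergeometric computation: the two-sided p-value is the sum of
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table (up to a small
#' relative tolerance against ties in floating point).
#'
#' @param table 2 x 2 integer matrix of counts, or the four counts
#'   `c(a, b, c, d)` row-wise.
#' @return List with `p_value`, `odds_ratio` (sample), and the table.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- if (is.matrix(table)) table else matrix(as.numeric(table), 2L,
                                               byrow = TRUE)
  if (!all(dim(x) == 2L) || any(x < 0) || any(x != round(x)))
    stop("need a 2 x 2 table of non-negative counts")
  a <- x[1, 1]; K <- sum(x[1, ]); N <- sum(x); k <- sum(x[, 1])
  lo <- max(0, k - (N - K)); hi <- min(k, K)
  support <- lo:hi
  probs <- dhyper(support, K, N - K, k)
  p_obs <- dhyper(a, K, N - K, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  list(p_value = min(1, p), odds_ratio = or, table = x)
}
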
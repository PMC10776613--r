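#' Bodywall muscle layout
#'
#' Orders the bodywall muscle cells along the anteroposterior axis within
#' their four bundles and records each cell's embryonic founder lineage
#' (MS, C, D or AB).
#'
#' @param layout data frame with columns `cell_id`, `bundle`, `rank`
#'   (anteroposterior rank within the bundle, consecutive from 1), and
#'   `founder`.
#' @return A validated `muscle_layout` data frame.
#' @export
muscle_layout <- function(layout) {
  l <- as.data.frame(layout)
  need <- c("cell_id", "bundle", "rank", "founder")
  miss <- setdiff(need, names(l))
  if (length(miss))
    stop("layout is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(l$cell_id)) stop("duplicate cell_id in layout")
  for (b in unique(l$bundle)) {
    r <- sort(l$rank[l$bundle == b])
    if (!identical(as.integer(r), seq_along(r)))
      stop("ranks must be consecutive from 1 within bundle ", b)
  }
  structure(l, class = c("muscle_layout", "data.frame"))
}

layout_levels <- function(matrix, layout, tf) {
  m <- unclass(as.matrix(matrix))
  miss <- setdiff(layout$cell_id, colnames(m))
  if (length(miss)) stop("layout cells absent from matrix: ",
                         paste(miss, collapse = ", "))
  m[tf, layout$cell_id]
}

#' Detect region-specific TFs along the bodywall muscle bundles
#'
#' A window of `window` consecutive anteroposterior ranks slides along
#' the four muscle bundles. A TF is region-specific if at some window
#' position every bundle has at least one cell expressed above
#' `fold`-fold background-equivalent (level > `log2(fold + 1)`) while
#' every muscle outside the window is undetectable (level 0).
#'
#' @param matrix an `expression_matrix` covering the muscle cells.
#' @param layout a [muscle_layout()].
#' @param window window length in cells (default 10).
#' @param fold expression threshold in background-equivalents (default 2).
#' @return Character vector of flagged TFs.
#' @export
detect_region_specific <- function(matrix, layout, window = 10L, fold = 2) {
  layout <- muscle_layout(layout)
  thr <- level_at_fold(fold)
  bundles <- unique(layout$bundle)
  max_rank <- max(layout$rank)
  flagged <- character(0L)
  for (tf in rownames(matrix)) {
    lv <- layout_levels(matrix, layout, tf)
    hit <- FALSE
    for (start in seq_len(max(1L, max_rank - window + 1L))) {
      inwin <- layout$rank >= start & layout$rank < start + window
      on_in <- vapply(bundles, function(b)
        any(lv[layout$bundle == b & inwin] > thr), logical(1L))
      if (all(on_in) && all(lv[!inwin] <= 0)) { hit <- TRUE; break }
    }
    if (hit) flagged <- c(flagged, tf)
  }
  flagged
}

#' Detect anteroposterior gradient TFs in the bodywall muscles
#'
#' Per bundle, expression level is regressed linearly on anteroposterior
#' rank. A TF is a gradient TF if, in more than one bundle, (i) the cell
#' at one end of the bundle is undetectable (level 0) and (ii) the slope's
#' p-value is below `p_cut`.
#'
#' @inheritParams detect_region_specific
#' @param p_cut slope p-value cutoff (default 1e-3).
#' @return Character vector of flagged TFs.
#' @export
detect_gradient <- function(matrix, layout, p_cut = 1e-3) {
  layout <- muscle_layout(layout)
  flagged <- character(0L)
  for (tf in rownames(matrix)) {
    lv <- layout_levels(matrix, layout, tf)
    n_ok <- 0L
    for (b in unique(layout$bundle)) {
      sel <- layout$bundle == b
      r <- layout$rank[sel]
      y <- lv[sel][order(r)]
      if (length(y) < 3L) next
      end_off <- y[1L] <= 0 || y[length(y)] <= 0
      if (!end_off || stats::var(y) == 0) next
      fit <- summary(lm(y ~ seq_along(y)))
      pv <- stats::coef(fit)[2L, 4L]
      if (is.finite(pv) && pv < p_cut) n_ok <- n_ok + 1L
    }
    if (n_ok > 1L) flagged <- c(flagged, tf)
  }
  flagged
}

#' Detect founder-lineage-related TFs in the bodywall muscles
#'
#' The single AB-derived bodywall muscle is excluded; remaining muscles
#' are grouped by founder blastomere. A TF is flagged for an ordered
#' founder pair when every muscle of one group expresses it at a higher
#' level than every muscle of the other group.
#'
#' @inheritParams detect_region_specific
#' @return Data frame with columns `tf`, `higher`, `lower`.
#' @export
detect_lineage_related <- function(matrix, layout) {
  layout <- muscle_layout(layout)
  layout <- layout[layout$founder != "AB", , drop = FALSE]
  groups <- split(layout$cell_id, layout$founder)
  out <- data.frame(tf = character(0L), higher = character(0L),
                    lower = character(0L), stringsAsFactors = FALSE)
  gn <- names(groups)
  for (tf in rownames(matrix)) {
    lv <- layout_levels(matrix, layout, tf)
    for (g1 in gn) for (g2 in setdiff(gn, g1)) {
      if (min(lv[groups[[g1]]]) > max(lv[groups[[g2]]]))
        out <- rbind(out, data.frame(tf = tf, higher = g1, lower = g2,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Detect stereotypically asymmetric TFs in bilateral cell pairs
#'
#' Per worm, a pair/TF is asymmetric when one mate's level exceeds
#' `fold`-fold background-equivalent (level > `log2(fold + 1)`) while the
#' other mate is undetectable (level 0). A pair/TF is called asymmetric
#' when at least `consensus` of the examined worms (a minimum of
#' `min_worms`) agree in the same direction. Asymmetric calls are then
#' tested for enrichment in lineage-convergent over lineage-symmetric
#' pairs with the exact two-sided Fisher test.
#'
#' @param levels_by_worm named list: per TF, a worms x cells matrix of
#'   expression levels (rows are individual worms).
#' @param pairs data frame with columns `pair_id`, `left_cell`,
#'   `right_cell`, and `lineage_class` (`"convergent"` or `"symmetric"`).
#' @param fold asymmetry threshold in background-equivalents (default 4).
#' @param min_worms minimum worms per tested pair/TF (default 8).
#' @param consensus fraction of worms that must agree (default 0.75).
#' @return List with `calls` (per pair/TF data frame) and `enrichment`
#'   (the 2 x 2 pair-level table and Fisher p-value).
#' @export
detect_asymmetric_pairs <- function(levels_by_worm, pairs, fold = 4,
                                    min_worms = 8L, consensus = 0.75) {
  pairs <- as.data.frame(pairs)
  need <- c("pair_id", "left_cell", "right_cell", "lineage_class")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs is missing columns: ",
                         paste(miss, collapse = ", "))
  thr <- level_at_fold(fold)
  calls <- NULL
  for (tf in names(levels_by_worm)) {
    lv <- levels_by_worm[[tf]]
    for (p in seq_len(nrow(pairs))) {
      lc <- pairs$left_cell[p]; rc <- pairs$right_cell[p]
      if (!all(c(lc, rc) %in% colnames(lv))) next
      L <- lv[, lc]; R <- lv[, rc]
      nw <- sum(is.finite(L) & is.finite(R))
      if (nw < min_worms) {
        warning("pair ", pairs$pair_id[p], " / ", tf,
                " excluded: only ", nw, " worms")
        next
      }
      left_only <- L > thr & R <= 0
      right_only <- R > thr & L <= 0
      frac_l <- sum(left_only) / nw
      frac_r <- sum(right_only) / nw
      called <- max(frac_l, frac_r) >= consensus
      direction <- if (!called) NA_character_
        else if (frac_l >= frac_r) "left" else "right"
      calls <- rbind(calls, data.frame(
        tf = tf, pair_id = pairs$pair_id[p],
        lineage_class = pairs$lineage_class[p],
        n_worms = nw, n_left = sum(left_only), n_right = sum(right_only),
        called = called, direction = direction, stringsAsFactors = FALSE))
    }
  }
  if (is.null(calls))
    calls <- data.frame(tf = character(0L), pair_id = character(0L),
                        lineage_class = character(0L), n_worms = integer(0L),
                        n_left = integer(0L), n_right = integer(0L),
                        called = logical(0L), direction = character(0L))
  # pair-level enrichment: pairs with >= 1 asymmetric TF call, by lineage class
  by_pair <- tapply(calls$called, calls$pair_id, any)
  pair_class <- pairs$lineage_class[match(names(by_pair), pairs$pair_id)]
  conv <- pair_class == "convergent"
  tab <- matrix(c(sum(by_pair[conv]), sum(!by_pair[conv]),
                  sum(by_pair[!conv]), sum(!by_pair[!conv])),
                2L, byrow = TRUE,
                dimnames = list(c("convergent", "symmetric"),
                                c("asymmetric", "not")))
  enr <- if (all(rowSums(tab) > 0)) fisher_exact_2x2(tab) else
    list(p_value = NA_real_, odds_ratio = NA_real_, table = tab)
  list(calls = calls, enrichment = enr)
}
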
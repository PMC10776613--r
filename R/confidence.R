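#' Per-cell annotation confidence (CAC) scores
#'
#' For every assigned identity, the anisotropic Gaussian score
#' `f_i = exp(-1/2 * sum_axis ((x_i - mu_i) / (alpha * sigma_i))^2)`
#' between the mapped subject point and its assigned template cell.
#' Identities left unassigned (missing nuclei) get CAC 0.
#'
#' @param assignment integer vector: template cell index per subject point
#'   (`NA` for outliers), or a `worm_annotation`.
#' @param mapped n x 3 mapped subject coordinates (ignored when
#'   `assignment` is a `worm_annotation`).
#' @param template a `worm_template`.
#' @param alpha smoothness constant (default 20).
#' @return Named numeric vector of length k (one CAC per template
#'   identity, in template order).
#' @export
cac <- function(assignment, mapped = NULL, template = NULL, alpha = 20) {
  if (inherits(assignment, "worm_annotation")) {
    ann <- assignment
    mapped <- ann$mapped
    assignment <- ann$assignment
    if (is.null(alpha)) alpha <- ann$alpha
  }
  x <- as_coords(mapped)
  k <- length(template$cell_ids)
  out <- setNames(numeric(k), template$cell_ids)
  ok <- which(!is.na(assignment))
  j <- assignment[ok]
  delta <- (x[ok, , drop = FALSE] - template$mean[j, , drop = FALSE]) /
    (alpha * template$sd[j, , drop = FALSE])
  out[j] <- exp(-0.5 * rowSums(delta^2))
  out
}

#' Worm annotation confidence (WAC) score
#'
#' The arithmetic mean of the per-cell CAC scores; for a full worm this
#' averages the 558 per-cell confidences.
#'
#' @param cac_scores numeric vector of CAC scores.
#' @return The mean, a real in \[0, 1\].
#' @export
wac <- function(cac_scores) {
  if (!length(cac_scores)) stop("empty CAC vector")
  mean(cac_scores)
}

#' Output-selection rule between RPM-based and bipartite-improved results
#'
#' Returns the bipartite-improved annotation when its WAC score reaches
#' the cutoff (inclusive), otherwise the RPM-based one. The bipartite
#' refinement only helps when the worm fits the template well; below the
#' cutoff it tends to degrade the initial matching.
#'
#' @param rpm,bipartite `worm_annotation`s of the same subject.
#' @param cutoff WAC cutoff (default 0.995).
#' @return The selected `worm_annotation` (its `mode` records which).
#' @export
select_output <- function(rpm, bipartite, cutoff = 0.995) {
  if (!identical(rpm$worm_id, bipartite$worm_id))
    stop("annotations come from different subjects")
  if (bipartite$wac >= cutoff) bipartite else rpm
}

#' Calibrate cell-specific CAC thresholds on a validation set
#'
#' For each cell identity with at least `min_support` validation
#' instances, candidate thresholds are the observed CAC values of its
#' incorrectly assigned instances; the threshold is the largest
#' candidate `t` such that assignment accuracy among instances with
#' CAC <= `t` is below 0.5. Anchoring candidates at errors keeps the
#' threshold at the top of the low-accuracy region instead of drifting
#' above isolated correct assignments. Identities whose low-confidence
#' assignments are still mostly correct get threshold 0 (never
#' flagged), as do under-supported identities (via
#' `default_threshold`).
#'
#' @param validation list of `list(annotation = worm_annotation,
#'   truth = named character vector)` pairs; `truth` maps subject point
#'   index to the true cell identity.
#' @param min_support minimum instances required to calibrate a cell
#'   (default 20).
#' @param default_threshold threshold assigned to under-supported cells
#'   (default 0).
#' @return A `cac_calibration`: data frame with `cell_id`, `threshold`,
#'   `support`, plus the default threshold as an attribute.
#' @export
calibrate_cac_thresholds <- function(validation, min_support = 20L,
                                     default_threshold = 0) {
  if (!length(validation)) stop("empty validation set")
  recs <- lapply(validation, function(v) {
    ann <- v$annotation
    truth <- v$truth
    cells <- assigned_cells(ann)
    ok <- !is.na(cells)
    idx <- which(ok)
    data.frame(cell_id = cells[idx],
               cac = ann$cac[cells[idx]],
               correct = truth[idx] == cells[idx],
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  all_cells <- unique(recs$cell_id)
  thr <- setNames(rep(default_threshold, length(all_cells)), all_cells)
  support <- setNames(integer(length(all_cells)), all_cells)
  for (cell in all_cells) {
    sub <- recs[recs$cell_id == cell, ]
    support[cell] <- nrow(sub)
    if (nrow(sub) < min_support) next
    thr[cell] <- 0
    for (t in sort(unique(sub$cac[!sub$correct]), decreasing = TRUE)) {
      at_or_below <- sub$correct[sub$cac <= t]
      if (mean(at_or_below) < 0.5) { thr[cell] <- t; break }
    }
  }
  structure(data.frame(cell_id = all_cells, threshold = as.numeric(thr),
                       support = as.integer(support),
                       stringsAsFactors = FALSE),
            default_threshold = default_threshold,
            class = c("cac_calibration", "data.frame"))
}

calibration_threshold <- function(calibration, cell_ids) {
  default <- attr(calibration, "default_threshold")
  if (is.null(default)) default <- 0
  thr <- calibration$threshold[match(cell_ids, calibration$cell_id)]
  thr[is.na(thr)] <- default
  thr
}

#' Flag low-confidence cells and re-assign around curated fixes (EPC)
#'
#' Error prediction and correction: cells whose CAC falls below their
#' calibrated threshold are flagged for curation. Curated fixes (cell
#' identity to subject point index) are pinned, and bipartite assignment
#' re-runs on the residual score submatrix with the pinned rows and
#' columns removed. CAC and WAC are recomputed for the result.
#'
#' @param annotation a `worm_annotation`.
#' @param template the `worm_template` it was annotated against.
#' @param calibration a `cac_calibration` (see
#'   [calibrate_cac_thresholds()]).
#' @param curated optional named integer vector: curated fixes mapping
#'   cell identity to subject point index; must be injective.
#' @return A `worm_annotation` with the `flagged` set recorded and, when
#'   fixes were supplied, identities re-assigned.
#' @export
epc_flag_and_reassign <- function(annotation, template, calibration,
                                  curated = NULL) {
  stopifnot(inherits(annotation, "worm_annotation"))
  thr <- calibration_threshold(calibration, template$cell_ids)
  flagged <- template$cell_ids[annotation$cac < thr]
  out <- annotation
  if (length(curated)) {
    cells <- names(curated)
    idx <- as.integer(curated)
    if (is.null(cells) || anyNA(match(cells, template$cell_ids)))
      stop("curated fixes must be named by template cell identities")
    if (anyDuplicated(cells) || anyDuplicated(idx))
      stop("conflicting curated fixes: mapping must be injective")
    f <- score_matrix(annotation$mapped, template, alpha = annotation$alpha)
    mah <- attr(f, "mahal")
    ci <- match(cells, template$cell_ids)
    free_rows <- setdiff(seq_len(nrow(f)), idx)
    free_cols <- setdiff(seq_len(ncol(f)), ci)
    assignment <- rep(NA_integer_, nrow(f))
    assignment[idx] <- ci
    if (length(free_rows) && length(free_cols)) {
      sub <- f[free_rows, free_cols, drop = FALSE]
      attr(sub, "mahal") <- mah[free_rows, free_cols, drop = FALSE]
      sub_assign <- bipartite_assign(sub)
      assignment[free_rows] <- free_cols[sub_assign]
    }
    out <- worm_annotation(assignment, template, annotation$mapped,
                           mode = annotation$mode, alpha = annotation$alpha,
                           worm_id = annotation$worm_id)
  }
  out$flagged <- flagged
  out
}

#' Annotation accuracy against ground truth
#'
#' `1 - N_error / k` with `k` the template size (558 for a full worm):
#' every template identity either assigned to the wrong nucleus or left
#' unassigned counts as an error.
#'
#' @param annotation a `worm_annotation`.
#' @param truth character vector of true identities, one per subject
#'   point.
#' @return Accuracy rate in \[0, 1\].
#' @export
annotation_accuracy <- function(annotation, truth) {
  k <- length(annotation$cell_ids)
  cells <- assigned_cells(annotation)
  ok <- !is.na(cells)
  n_correct <- sum(cells[ok] == truth[ok])
  1 - (k - n_correct) / k
}
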
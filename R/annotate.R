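#' Anisotropic Gaussian matching-score matrix
#'
#' Scores every mapped subject point against every template cell with
#' `f_ij = exp(-1/2 * sum_axis ((x_i - mu_j) / (alpha * sigma_j))^2)`.
#' The smoothness constant `alpha` scales the template SDs so that the
#' score field stays informative far from the mean; the default is 20.
#'
#' @param mapped n x 3 matrix of subject coordinates in template space.
#' @param template a `worm_template`.
#' @param alpha positive smoothness constant (default 20).
#' @return n x k score matrix in \[0, 1\] with attribute `mahal`, the
#'   underlying squared Mahalanobis distances, and `alpha`.
#' @export
score_matrix <- function(mapped, template, alpha = 20) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  x <- as_coords(mapped)
  mu <- template$mean
  sds <- template$sd * alpha
  mah <- matrix(0, nrow(x), nrow(mu))
  for (a in 1:3)
    mah <- mah + sweep(outer(x[, a], mu[, a], "-")^2, 2L, sds[, a]^2, "/")
  f <- exp(-0.5 * mah)
  colnames(f) <- template$cell_ids
  attr(f, "mahal") <- mah
  attr(f, "alpha") <- alpha
  f
}

#' Maximum-score bipartite assignment
#'
#' Solves the linear assignment problem maximizing the total matching
#' score (Hungarian algorithm on the negated scores). Non-square matrices
#' are padded with zero-score slack rows/columns: extra subject points are
#' absorbed as outliers (`NA` in the result) and unmatched template
#' identities are reported via the `missing` attribute. Near-zero score
#' blocks are regularized with a secondary key `-1e-12 * Mahalanobis`
#' (when the matrix carries a `mahal` attribute) so that far-field
#' assignments remain geometrically sensible and deterministic.
#'
#' @param scores n x k score matrix (e.g. from [score_matrix()]).
#' @return Integer vector of length n giving the assigned column (template
#'   cell index) for each row, `NA` for slack-absorbed rows; attribute
#'   `missing` lists unassigned column indices when n < k.
#' @export
bipartite_assign <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  util <- scores
  mah <- attr(scores, "mahal")
  if (!is.null(mah)) {
    mah[!is.finite(mah)] <- 1e12
    util <- util - 1e-12 * mah
  }
  m <- max(n, k)
  cost <- matrix(0, m, m)
  cost[seq_len(n), seq_len(k)] <- -util
  j <- .lsap_min(cost)
  out <- j[seq_len(n)]
  out[out > k] <- NA_integer_
  if (n < k) {
    assigned <- out[!is.na(out)]
    attr(out, "missing") <- setdiff(seq_len(k), assigned)
  }
  out
}

#' Construct an annotation object
#'
#' @param assignment integer vector: template cell index assigned to each
#'   subject point (`NA` for outliers).
#' @param template the `worm_template` annotated against.
#' @param mapped n x 3 matrix of subject coordinates in template space.
#' @param mode `"rpm"` or `"bipartite"`.
#' @param alpha smoothness constant used for confidence scores.
#' @param worm_id subject worm identifier.
#' @return A `worm_annotation` with per-cell CAC scores, their mean (the
#'   WAC score), and an empty flag set.
#' @export
worm_annotation <- function(assignment, template, mapped,
                            mode = c("bipartite", "rpm"), alpha = 20,
                            worm_id = "worm") {
  mode <- match.arg(mode)
  cc <- cac(assignment, mapped, template, alpha = alpha)
  structure(list(assignment = assignment,
                 cell_ids = template$cell_ids,
                 mapped = as_coords(mapped),
                 mode = mode, alpha = alpha,
                 cac = cc, wac = wac(cc),
                 flagged = character(0L),
                 worm_id = as.character(worm_id)),
            class = "worm_annotation")
}

#' @export
print.worm_annotation <- function(x, ...) {
  cat(sprintf("<worm_annotation> worm '%s' (%s): %d/%d identities assigned, WAC %.4f\n",
              x$worm_id, x$mode, sum(!is.na(x$assignment)),
              length(x$cell_ids), x$wac))
  if (length(x$flagged))
    cat("  flagged:", length(x$flagged), "cells below their CAC threshold\n")
  invisible(x)
}

#' @export
summary.worm_annotation <- function(object, ...) {
  cat(sprintf("Annotation of worm '%s' (mode %s)\n", object$worm_id, object$mode))
  cat(sprintf("  identities assigned : %d of %d\n",
              sum(!is.na(object$assignment)), length(object$cell_ids)))
  cat(sprintf("  WAC                 : %.6f\n", object$wac))
  q <- quantile(object$cac, c(0, .25, .5, .75, 1), na.rm = TRUE)
  cat(sprintf("  CAC quartiles       : %.3f / %.3f / %.3f / %.3f / %.3f\n",
              q[1], q[2], q[3], q[4], q[5]))
  if (length(object$flagged))
    cat("  flagged cells       :", paste(object$flagged, collapse = ", "), "\n")
  invisible(object)
}

# cells assigned to each subject point, as identity names
assigned_cells <- function(annotation) {
  ifelse(is.na(annotation$assignment), NA_character_,
         annotation$cell_ids[annotation$assignment])
}

#' Annotate a worm image stack against one template
#'
#' Runs the full pipeline: PCA rigid pre-alignment, RPM deterministic
#' annealing for the initial correspondence (the RPM-based annotation),
#' then `iterations` rounds of global affine refit, sliding-window
#' piecewise affine remapping, anisotropic Gaussian scoring and bipartite
#' re-assignment (the bipartite-improved annotation). The default of three
#' refinement iterations follows the tool's standard operating point.
#'
#' @param subject a `point_set` of segmented nucleus centroids.
#' @param template a `worm_template`.
#' @param alpha smoothness constant for scores and confidence (default 20).
#' @param iterations refinement iterations (default 3).
#' @param cfg an [rpm_config()].
#' @param window_frac,step_frac,min_window_points piecewise-affine
#'   parameters (see [piecewise_affine_map()]).
#' @return A list with elements `rpm` and `bipartite`, both
#'   `worm_annotation`s carrying CAC and WAC scores.
#' @export
annotate_stack <- function(subject, template, alpha = 20, iterations = 3L,
                           cfg = rpm_config(), window_frac = 1 / 8,
                           step_frac = 1 / 8, min_window_points = 8L) {
  stopifnot(inherits(subject, "point_set"), inherits(template, "worm_template"))
  al <- pca_rigid_align(subject, template)
  corr <- rpm_correspond(al$aligned, template, cfg)
  map_once <- function(pairs) {
    ok <- !is.na(pairs)
    gtf <- fit_global_affine(al$aligned[ok, , drop = FALSE],
                             template$mean[pairs[ok], , drop = FALSE])
    piecewise_affine_map(al$aligned, template, pairs,
                         window_frac = window_frac, step_frac = step_frac,
                         min_window_points = min_window_points,
                         global_tf = gtf)
  }
  rpm_mapped <- map_once(corr$pairs)
  rpm_ann <- worm_annotation(corr$pairs, template, rpm_mapped,
                             mode = "rpm", alpha = alpha,
                             worm_id = subject$worm_id)
  pairs <- corr$pairs
  mapped <- rpm_mapped
  for (it in seq_len(iterations)) {
    mapped <- map_once(pairs)
    f <- score_matrix(mapped, template, alpha = alpha)
    pairs <- bipartite_assign(f)
  }
  bip_ann <- worm_annotation(pairs, template, mapped,
                             mode = "bipartite", alpha = alpha,
                             worm_id = subject$worm_id)
  list(rpm = rpm_ann, bipartite = bip_ann)
}

#' Annotate a stack against several templates and keep the best result
#'
#' Annotates the subject independently against each template, applies the
#' WAC output-selection rule to each ([select_output()]), and returns the
#' selected annotation with the highest WAC score. The per-template WACs
#' are recorded in the `per_template_wac` attribute.
#'
#' @param subject a `point_set`.
#' @param templates list of `worm_template`s (>= 1).
#' @param cutoff WAC cutoff for the bipartite-vs-RPM output rule.
#' @param ... passed to [annotate_stack()].
#' @return The selected `worm_annotation`.
#' @export
annotate_multi <- function(subject, templates, cutoff = 0.995, ...) {
  if (!length(templates)) stop("need at least one template")
  results <- lapply(templates, function(tpl) {
    both <- annotate_stack(subject, tpl, ...)
    select_output(both$rpm, both$bipartite, cutoff = cutoff)
  })
  wacs <- vapply(results, function(a) a$wac, numeric(1L))
  best <- which.max(wacs)
  out <- results[[best]]
  attr(out, "per_template_wac") <- wacs
  attr(out, "template_index") <- best
  out
}
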
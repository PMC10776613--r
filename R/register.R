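#' Configuration for robust point matching (RPM)
#'
#' Parameters of the deterministic-annealing soft-assignment loop. The
#' initial temperature is `T_init_factor` times the squared maximum pairwise
#' distance divided by the number of template cells; the final temperature is
#' `T_final_factor` times the squared mean template SD. Annealing multiplies
#' the temperature by `anneal_rate` each outer iteration until it falls below
#' the final temperature (or `outer_iters` is reached).
#'
#' @param T_init_factor,T_final_factor positive multipliers of the
#'   data-derived initial/final temperatures.
#' @param anneal_rate geometric cooling rate in (0, 1).
#' @param sinkhorn_iters row/column normalization sweeps per temperature.
#' @param outer_iters cap on annealing steps (default: run the schedule out).
#' @return A list of class `rpm_config`.
#' @export
rpm_config <- function(T_init_factor = 1, T_final_factor = 1,
                       anneal_rate = 0.93, sinkhorn_iters = 30L,
                       outer_iters = Inf) {
  if (!(anneal_rate > 0 && anneal_rate < 1))
    stop("anneal_rate must be in (0, 1)")
  if (!(T_init_factor > 0 && T_final_factor > 0))
    stop("temperature factors must be positive")
  if (sinkhorn_iters < 1L) stop("sinkhorn_iters must be >= 1")
  structure(list(T_init_factor = T_init_factor,
                 T_final_factor = T_final_factor,
                 anneal_rate = anneal_rate,
                 sinkhorn_iters = as.integer(sinkhorn_iters),
                 outer_iters = outer_iters),
            class = "rpm_config")
}

# squared Euclidean cross-distance matrix between rows of x (n x 3), y (k x 3)
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

#' Rigidly pre-align a subject point set to a target by principal axes
#'
#' Centres the subject on the target centroid and rotates its principal
#' axes onto the target's. Principal axes leave a four-fold sign ambiguity
#' among right-handed frames; the candidate minimizing the symmetric mean
#' nearest-neighbour distance to the target is returned. The rotation
#' always has determinant +1 (no reflection).
#'
#' @param subject a `point_set` (or n x 3 matrix).
#' @param target a `worm_template`, `point_set`, or k x 3 matrix.
#' @return A list with `aligned` (n x 3 matrix), `rotation` (3 x 3, det +1),
#'   `translation` (length 3), and `cost` (the nearest-neighbour criterion).
#' @export
pca_rigid_align <- function(subject, target) {
  x <- as_coords(subject)
  y <- as_coords(target)
  if (nrow(x) < 4L || nrow(y) < 4L)
    stop("need at least 4 points in both sets")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  ex <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  ey <- eigen(crossprod(yc) / (nrow(yc) - 1), symmetric = TRUE)
  if (min(ex$values) < 1e-12 * max(ex$values) ||
      min(ey$values) < 1e-12 * max(ey$values))
    stop("degenerate geometry: rank-deficient covariance")
  Vx <- ex$vectors; Vy <- ey$vectors
  best <- NULL
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  for (r in seq_len(nrow(signs))) {
    S <- diag(as.numeric(signs[r, ]))
    R <- Vy %*% S %*% t(Vx)
    if (det(R) < 0) next                   # keep right-handed frames only
    aligned <- xc %*% t(R)
    aligned[, 1L] <- aligned[, 1L] + cy[1L]
    aligned[, 2L] <- aligned[, 2L] + cy[2L]
    aligned[, 3L] <- aligned[, 3L] + cy[3L]
    d2 <- cross_dist2(aligned, y)
    rmin <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, "first"))]
    td2 <- t(d2)
    cmin <- td2[cbind(seq_len(nrow(td2)), max.col(-td2, "first"))]
    cost <- (mean(sqrt(rmin)) + mean(sqrt(cmin))) / 2
    if (is.null(best) || cost < best$cost)
      best <- list(aligned = aligned, rotation = R, cost = cost)
  }
  translation <- as.numeric(cy - best$rotation %*% cx)
  colnames(best$aligned) <- c("x", "y", "z")
  list(aligned = best$aligned, rotation = best$rotation,
       translation = translation, cost = best$cost)
}

#' Initial correspondence by deterministic-annealing robust point matching
#'
#' Alternates (a) a soft-assignment update
#' `m_ij ~ exp(-||x_i - A(mu_j)||^2 / (2T))`, normalized towards a doubly
#' stochastic matrix with one outlier slack row and column by alternating
#' row/column scaling, and (b) a weighted least-squares update of the affine
#' map `A` from template means to subject points, while annealing the
#' temperature `T` geometrically. The final soft matrix is rounded to a hard
#' bijection by maximum-score bipartite matching.
#'
#' @param subject a pre-aligned `point_set` or n x 3 matrix (see
#'   [pca_rigid_align()]).
#' @param template a `worm_template`.
#' @param cfg an [rpm_config()].
#' @return A list of class `correspondence`: `pairs` (integer vector, the
#'   template cell index matched to each subject point, `NA` for outliers),
#'   `soft` (final n x k soft-assignment matrix), `affine`
#'   (template-to-subject `affine3d`), and `mode = "rpm"`.
#' @export
rpm_correspond <- function(subject, template, cfg = rpm_config()) {
  if (!inherits(cfg, "rpm_config")) stop("cfg must be an rpm_config")
  x <- as_coords(subject)
  mu <- template$mean
  n <- nrow(x); k <- nrow(mu)
  T_init <- cfg$T_init_factor * max(cross_dist2(x, x)) / k
  T_final <- cfg$T_final_factor * mean(template$sd)^2
  if (!(T_init > T_final))
    stop("invalid annealing schedule: initial temperature not above final")
  A <- affine_identity()
  muh <- cbind(mu, 1)
  Temp <- T_init
  iter <- 0L
  m <- NULL
  slack <- exp(-0.5)   # outlier prior: matches a point ~sqrt(T) away
  while (Temp > T_final && iter < cfg$outer_iters) {
    iter <- iter + 1L
    d2 <- cross_dist2(x, apply_affine(A, mu))
    # soft assignment with outlier slack row/column, normalized towards
    # doubly stochastic by alternating row/column scaling (compiled)
    m <- .softassign(d2, Temp, slack, cfg$sinkhorn_iters)
    w <- m[seq_len(n), seq_len(k), drop = FALSE]
    # weighted LS update of A: minimize sum_ij w_ij ||A mu_j - x_i||^2
    cw <- colSums(w)
    G <- crossprod(muh, muh * cw)         # 4 x 4
    B <- crossprod(muh, crossprod(w, x))  # 4 x 3
    A <- affine3d(t(solve(G + 1e-9 * diag(4L), B)))
    Temp <- Temp * cfg$anneal_rate
  }
  soft <- m[seq_len(n), seq_len(k), drop = FALSE]
  pairs <- bipartite_assign(soft)
  structure(list(pairs = pairs, soft = soft, affine = A,
                 mode = "rpm", iterations = iter,
                 T_init = T_init, T_final = T_final),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("<correspondence> mode %s: %d/%d points matched\n",
              x$mode, sum(!is.na(x$pairs)), length(x$pairs)))
  invisible(x)
}

#' Sliding-window piecewise affine remapping onto a template
#'
#' Windows of length `window_frac` times the template's anteroposterior
#' extent slide along the template X axis in steps of `step_frac` times the
#' window length. Within each window, the template cells whose mean X lies
#' inside (half-open intervals, the last window closed) and their
#' corresponded subject points are fit by a local affine (subject to
#' template) and the subject points mapped; each subject point's final
#' position is the unweighted average of its mapped positions over all
#' windows containing its corresponded template cell. Windows with fewer
#' than `min_window_points` pairs (or a degenerate local fit) fall back to
#' the global affine.
#'
#' @param subject n x 3 coordinate matrix (or `point_set`), already
#'   globally registered to the template.
#' @param template a `worm_template`.
#' @param pairs integer vector: template cell index corresponded to each
#'   subject point (`NA` for unmatched points, which are mapped by the
#'   global transform).
#' @param window_frac,step_frac window length and step as fractions of the
#'   template extent and the window length, respectively; defaults 1/8 and
#'   1/8 (so the step is 1/64 of the template length).
#' @param min_window_points minimum pairs for a local fit (default 8).
#' @param global_tf optional `affine3d` fallback; by default fit from all
#'   corresponded pairs.
#' @return The remapped n x 3 coordinate matrix.
#' @export
piecewise_affine_map <- function(subject, template, pairs,
                                 window_frac = 1 / 8, step_frac = 1 / 8,
                                 min_window_points = 8L, global_tf = NULL) {
  x <- as_coords(subject)
  if (!(window_frac > 0 && window_frac <= 1) ||
      !(step_frac > 0 && step_frac <= 1))
    stop("window_frac and step_frac must be in (0, 1]")
  n <- nrow(x)
  if (length(pairs) != n) stop("pairs must have one entry per subject point")
  mu <- template$mean
  ok <- !is.na(pairs)
  if (is.null(global_tf)) {
    global_tf <- fit_global_affine(x[ok, , drop = FALSE],
                                   mu[pairs[ok], , drop = FALSE])
  }
  tx <- mu[, 1L]
  x0 <- min(tx); x1 <- max(tx)
  L <- x1 - x0
  if (L <= 0) return(apply_affine(global_tf, x))
  wl <- window_frac * L
  step <- step_frac * wl
  starts <- seq(x0, x1 - wl, by = step)
  if (max(starts) + wl < x1) starts <- c(starts, x1 - wl)
  nw <- length(starts)
  acc <- matrix(0, n, 3L)
  cnt <- numeric(n)
  for (w in seq_len(nw)) {
    s <- starts[w]
    inwin <- if (w == nw) tx >= s & tx <= s + wl else tx >= s & tx < s + wl
    sel <- ok & inwin[pmax(pairs, 1L)] & !is.na(pairs)
    sel[is.na(sel)] <- FALSE
    tf <- global_tf
    if (sum(sel) >= min_window_points) {
      tf <- tryCatch(
        fit_global_affine(x[sel, , drop = FALSE],
                          mu[pairs[sel], , drop = FALSE]),
        error = function(e) global_tf)
    }
    if (any(sel)) {
      acc[sel, ] <- acc[sel, , drop = FALSE] +
        apply_affine(tf, x[sel, , drop = FALSE])
      cnt[sel] <- cnt[sel] + 1
    }
  }
  out <- matrix(NA_real_, n, 3L)
  hit <- cnt > 0
  out[hit, ] <- acc[hit, , drop = FALSE] / cnt[hit]
  if (any(!hit)) out[!hit, ] <- apply_affine(global_tf, x[!hit, , drop = FALSE])
  colnames(out) <- c("x", "y", "z")
  out
}
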
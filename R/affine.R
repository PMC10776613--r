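#' Fit a 12-parameter 3D affine transform between corresponding points
#'
#' Least-squares estimate of the 3 x 4 matrix `M` (acting on homogeneous
#' coordinates) minimizing the sum of squared residuals
#' `sum(|| M [src, 1]' - dst' ||^2)` over the given correspondences.
#'
#' @param src,dst numeric n x 3 coordinate matrices (or `point_set`s).
#' @param correspondence optional two-column integer matrix of (src row,
#'   dst row) index pairs; default pairs row i with row i.
#' @param weights optional non-negative per-pair weights for a weighted fit.
#' @return An `affine3d` object: a 3 x 4 matrix with the linear block in
#'   columns 1-3 and the translation in column 4.
#' @examples
#' pts <- matrix(rnorm(24), 8, 3)
#' M <- fit_global_affine(pts, pts)   # identity
#' @export
fit_global_affine <- function(src, dst, correspondence = NULL, weights = NULL) {
  src <- as_coords(src); dst <- as_coords(dst)
  if (is.null(correspondence)) {
    if (nrow(src) != nrow(dst))
      stop("src and dst differ in size; supply a correspondence")
    correspondence <- cbind(seq_len(nrow(src)), seq_len(nrow(src)))
  }
  correspondence <- as.matrix(correspondence)
  if (ncol(correspondence) != 2L)
    stop("correspondence must be a two-column index matrix")
  x <- src[correspondence[, 1L], , drop = FALSE]
  y <- dst[correspondence[, 2L], , drop = FALSE]
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 corresponding point pairs")
  X <- cbind(x, 1)
  if (!is.null(weights)) {
    w <- sqrt(as.numeric(weights))
    if (length(w) != n) stop("weights length must match pair count")
    X <- X * w
    y <- y * w
  }
  # rank check guards coplanar/collinear configurations
  if (qr(X)$rank < 4L)
    stop("degenerate geometry: corresponding points are coplanar or collinear")
  fit <- lm.fit(X, y)
  M <- t(fit$coefficients)          # 3 x 4
  dimnames(M) <- NULL
  if (abs(det(M[, 1:3])) < 1e-12)
    stop("singular affine fit: linear block is rank deficient")
  affine3d(M)
}

#' Create an affine transform object
#'
#' @param M numeric 3 x 4 matrix (linear block | translation).
#' @return An `affine3d` object.
#' @export
affine3d <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(3L, 4L))) stop("affine matrix must be 3 x 4")
  structure(M, class = c("affine3d", "matrix"))
}

#' Identity affine transform
#' @return An `affine3d` performing no transformation.
#' @export
affine_identity <- function() affine3d(cbind(diag(3), 0))

#' Apply an affine transform to coordinates
#'
#' @param transform an `affine3d` object.
#' @param coords numeric n x 3 matrix (or `point_set`).
#' @return Transformed n x 3 coordinate matrix.
#' @export
apply_affine <- function(transform, coords) {
  coords <- as_coords(coords)
  out <- coords %*% t(transform[, 1:3, drop = FALSE])
  out[, 1L] <- out[, 1L] + transform[1L, 4L]
  out[, 2L] <- out[, 2L] + transform[2L, 4L]
  out[, 3L] <- out[, 3L] + transform[3L, 4L]
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> 12-parameter 3D affine transform\n")
  print(unclass(x))
  invisible(x)
}
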
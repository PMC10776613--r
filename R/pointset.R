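#' Construct a worm point set
#'
#' A point set holds the segmented-nucleus centroids of one straightened worm
#' in micrometres (X = anteroposterior, Y = dorsoventral, Z = left-right),
#' with optional per-nucleus channel intensities and optional ground-truth
#' cell-identity labels.
#'
#' @param coords numeric n x 3 matrix of centroid coordinates (um).
#' @param worm_id character scalar identifying the worm.
#' @param labels optional character vector of cell identities, one per point;
#'   must be unique within the worm.
#' @param intensities optional data frame of per-nucleus channel means
#'   (e.g. columns `dapi`, `reporter`), one row per point.
#' @return An object of class `point_set`.
#' @export
point_set <- function(coords, worm_id = "worm", labels = NULL,
                      intensities = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 4L)
    stop("a point set needs at least 4 points")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(coords))
      stop("labels length must match the number of points")
    dup <- labels[duplicated(labels)]
    if (length(dup))
      stop("duplicate cell labels within worm: ",
           paste(unique(dup), collapse = ", "))
  }
  if (!is.null(intensities)) {
    intensities <- as.data.frame(intensities)
    if (nrow(intensities) != nrow(coords))
      stop("intensities must have one row per point")
  }
  structure(
    list(worm_id = as.character(worm_id), coords = coords,
         labels = labels, intensities = intensities),
    class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> worm '%s': %d nuclei%s%s\n",
              x$worm_id, nrow(x$coords),
              if (!is.null(x$labels)) ", labelled" else "",
              if (!is.null(x$intensities))
                paste0(", intensities [",
                       paste(names(x$intensities), collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @export
length.point_set <- function(x) nrow(x$coords)

as_coords <- function(x) {
  if (inherits(x, "point_set")) x$coords
  else if (inherits(x, "worm_template")) x$mean
  else as.matrix(x)
}

# index of each template cell id in a labelled point set (error if absent)
label_index <- function(ps, cell_ids) {
  if (is.null(ps$labels))
    stop("point set '", ps$worm_id, "' has no cell labels")
  idx <- match(cell_ids, ps$labels)
  if (anyNA(idx))
    stop("worm '", ps$worm_id, "' is missing identities: ",
         paste(head(cell_ids[is.na(idx)], 5L), collapse = ", "))
  idx
}
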
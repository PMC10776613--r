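#' Read a worm point set from a TSV file
#'
#' Expects a tab-separated file with header columns `nucleus_index x y z`
#' and optionally `dapi`, `reporter`, and `cell_id`. Row order is
#' preserved. With `voxel_to_um = TRUE` the coordinates are converted
#' from pixels to micrometres using the confocal sampling sizes
#' (0.116 um in X-Y, 0.122 um in Z by default).
#'
#' @param path input file path.
#' @param voxel_to_um convert pixel coordinates to um (default FALSE).
#' @param voxel_size length-3 sampling size in um/pixel.
#' @param worm_id worm identifier (default: file name without extension).
#' @return A `point_set`.
#' @export
read_pointset <- function(path, voxel_to_um = FALSE,
                          voxel_size = c(0.116, 0.116, 0.122),
                          worm_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("nucleus_index", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("point-set file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (col in c("x", "y", "z")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric ", col, " in ", path, " at data line ",
           paste(bad, collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (voxel_to_um) coords <- sweep(coords, 2L, voxel_size, "*")
  labels <- if ("cell_id" %in% names(df)) {
    dup <- which(duplicated(df$cell_id))
    if (length(dup))
      stop("duplicate cell_id '", df$cell_id[dup[1L]], "' in ", path,
           " at data line ", dup[1L])
    df$cell_id
  }
  intensities <- if (all(c("dapi", "reporter") %in% names(df)))
    df[, c("dapi", "reporter")]
  if (is.null(worm_id))
    worm_id <- sub("\\.[^.]*$", "", basename(path))
  point_set(coords, worm_id = worm_id, labels = labels,
            intensities = intensities)
}

#' Write a point set to a TSV file
#' @param ps a `point_set`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_pointset <- function(ps, path) {
  df <- data.frame(nucleus_index = seq_len(nrow(ps$coords)) - 1L,
                   x = sprintf("%.6f", ps$coords[, 1L]),
                   y = sprintf("%.6f", ps$coords[, 2L]),
                   z = sprintf("%.6f", ps$coords[, 3L]),
                   stringsAsFactors = FALSE)
  if (!is.null(ps$intensities)) df <- cbind(df, ps$intensities)
  if (!is.null(ps$labels)) df$cell_id <- ps$labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a worm template from a TSV file
#'
#' Format: header `cell_id mx my mz sx sy sz`, positions and SDs in um.
#' @param path input file path.
#' @param sd_floor minimum per-axis SD in um.
#' @return A `worm_template`.
#' @export
read_template <- function(path, sd_floor = 0.1) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "mx", "my", "mz", "sx", "sy", "sz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("template file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  worm_template(df$cell_id, as.matrix(df[, c("mx", "my", "mz")]),
                as.matrix(df[, c("sx", "sy", "sz")]),
                provenance = paste("read from", basename(path)),
                sd_floor = sd_floor)
}

#' Write a worm template to a TSV file
#' @param template a `worm_template`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_template <- function(template, path) {
  df <- data.frame(cell_id = template$cell_ids,
                   mx = sprintf("%.6f", template$mean[, 1L]),
                   my = sprintf("%.6f", template$mean[, 2L]),
                   mz = sprintf("%.6f", template$mean[, 3L]),
                   sx = sprintf("%.6f", template$sd[, 1L]),
                   sy = sprintf("%.6f", template$sd[, 2L]),
                   sz = sprintf("%.6f", template$sd[, 3L]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation to a TSV file
#'
#' Format: `subject_index cell_id cac flagged mode`, CAC at 6 decimals,
#' rows ordered by subject index (0-based).
#'
#' @param annotation a `worm_annotation`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  cells <- assigned_cells(annotation)
  cacv <- ifelse(is.na(cells), 0, annotation$cac[match(cells, annotation$cell_ids)])
  df <- data.frame(subject_index = seq_along(cells) - 1L,
                   cell_id = ifelse(is.na(cells), "unassigned", cells),
                   cac = sprintf("%.6f", cacv),
                   flagged = as.integer(!is.na(cells) & cells %in% annotation$flagged),
                   mode = annotation$mode,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation table written by [write_annotation()]
#' @param path input file path.
#' @return Data frame with `subject_index`, `cell_id`, `cac`, `flagged`,
#'   `mode`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_index", "cell_id", "cac", "flagged", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  df
}

#' Write an expression matrix to a TSV file (rows = TFs, columns = cells)
#' @param matrix an `expression_matrix`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(tf = rownames(matrix),
                   unclass(as.matrix(matrix)), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#' @param path input file path.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, class = c("expression_matrix", "matrix"))
}

#' Write a CAC calibration table to a TSV file
#' @param calibration a `cac_calibration`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  df <- data.frame(cell_id = calibration$cell_id,
                   threshold = sprintf("%.6f", calibration$threshold),
                   support = calibration$support, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CAC calibration table
#' @param path input file path.
#' @param default_threshold threshold for cells absent from the table.
#' @return A `cac_calibration`.
#' @export
read_calibration <- function(path, default_threshold = 0) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(data.frame(cell_id = df$cell_id,
                       threshold = as.numeric(df$threshold),
                       support = as.integer(df$support),
                       stringsAsFactors = FALSE),
            default_threshold = default_threshold,
            class = c("cac_calibration", "data.frame"))
}
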
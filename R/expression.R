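#' Quantify reporter expression levels for one annotated image stack
#'
#' Background reporter fluorescence is estimated as the mean over the
#' pseudonuclei (manually placed background regions, ten by default in
#' practice). Background-subtracted reporter fluorescence is normalized by
#' each nucleus's DAPI fluorescence to correct for spherical aberration,
#' rescaled by the worm's median DAPI so the result stays on the intensity
#' scale, clamped at zero ("undetectable"), and converted to an expression
#' level `log2((normalized_f + 500) / 500)`: a normalized fluorescence of
#' 500 is barely distinguishable from background, giving level 1.
#'
#' @param measurement data frame with columns `cell_id`, `dapi`,
#'   `reporter`, and logical/0-1 `is_pseudo` marking pseudonuclei;
#'   optionally `worm_id` and `nucleus_index`.
#' @return Named numeric vector of expression levels per cell identity,
#'   with attribute `background` (the pseudonucleus mean).
#' @export
quantify_stack <- function(measurement) {
  m <- as.data.frame(measurement)
  need <- c("cell_id", "dapi", "reporter", "is_pseudo")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("measurement is missing columns: ", paste(miss, collapse = ", "))
  pseudo <- as.logical(m$is_pseudo)
  if (!any(pseudo)) stop("measurement has no pseudonuclei for background")
  bg <- mean(m$reporter[pseudo])
  nuc <- m[!pseudo, , drop = FALSE]
  bad <- which(!(nuc$dapi > 0))
  if (length(bad))
    stop("non-positive DAPI fluorescence for nucleus: ",
         paste(nuc$cell_id[bad], collapse = ", "))
  dapi_ref <- median(nuc$dapi)
  nf <- pmax(0, (nuc$reporter - bg) / nuc$dapi * dapi_ref)
  levels <- log2((nf + 500) / 500)
  structure(setNames(levels, nuc$cell_id), background = bg)
}

# reporter classes in decreasing faithfulness to the endogenous gene
REPORTER_CLASSES <- c("knockin_fosmid", "high_context_promoter",
                      "low_context_promoter")

#' Aggregate per-stack levels into a TF x cell expression matrix
#'
#' The profile of a strain is the mean of its stacks' level vectors; the
#' profile of a transcription factor is the mean over its strains of the
#' most faithful reporter class present (knock-in/fosmid fusions over
#' high-context promoter fusions over low-context promoter fusions).
#' Germline cells are dropped (transgene silencing), leaving the 556
#' somatic cells for a full worm.
#'
#' @param stacks named list of per-stack level vectors (from
#'   [quantify_stack()]); all stacks must cover the same cell identities.
#' @param meta data frame with one row per stack: `stack_id` (matching
#'   `names(stacks)`), `strain`, `tf`, and `reporter_class` (one of
#'   `r paste(REPORTER_CLASSES, collapse = ", ")`).
#' @param germline cell identities to exclude (default `Z2`, `Z3`).
#' @return An `expression_matrix`: numeric TF x cell matrix with attribute
#'   `reporter_class` giving the class used per TF.
#' @export
aggregate_profiles <- function(stacks, meta, germline = c("Z2", "Z3")) {
  meta <- as.data.frame(meta)
  need <- c("stack_id", "strain", "tf", "reporter_class")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("meta is missing columns: ", paste(miss, collapse = ", "))
  if (!all(meta$reporter_class %in% REPORTER_CLASSES))
    stop("unknown reporter_class; expected one of: ",
         paste(REPORTER_CLASSES, collapse = ", "))
  if (!all(meta$stack_id %in% names(stacks)))
    stop("meta references stacks not supplied")
  cells <- names(stacks[[1L]])
  for (s in stacks)
    if (!identical(sort(names(s)), sort(cells)))
      stop("all stacks must cover the same cell identities")
  keep <- setdiff(cells, germline)
  tfs <- unique(meta$tf)
  out <- matrix(NA_real_, length(tfs), length(keep),
                dimnames = list(tfs, keep))
  class_used <- setNames(character(length(tfs)), tfs)
  dropped <- character(0L)
  for (tf in tfs) {
    mt <- meta[meta$tf == tf, , drop = FALSE]
    if (!nrow(mt)) { dropped <- c(dropped, tf); next }
    best <- REPORTER_CLASSES[min(match(mt$reporter_class, REPORTER_CLASSES))]
    mt <- mt[mt$reporter_class == best, , drop = FALSE]
    strain_profiles <- vapply(unique(mt$strain), function(st) {
      ids <- mt$stack_id[mt$strain == st]
      rowMeans(vapply(ids, function(i) stacks[[i]][keep],
                      numeric(length(keep))))
    }, numeric(length(keep)))
    out[tf, ] <- rowMeans(as.matrix(strain_profiles))
    class_used[tf] <- best
  }
  if (length(dropped)) {
    warning("TFs with no strains omitted: ", paste(dropped, collapse = ", "))
    out <- out[!rownames(out) %in% dropped, , drop = FALSE]
    class_used <- class_used[!names(class_used) %in% dropped]
  }
  structure(out, reporter_class = class_used,
            class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d TFs x %d cells (log2 levels)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

# expression level corresponding to "fold x background-equivalent":
# a normalized fluorescence of fold*500 gives log2(fold + 1)
level_at_fold <- function(fold) log2(fold + 1)
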
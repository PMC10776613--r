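#' Configuration for the synthetic worm generator
#'
#' Defines the study conditions for ground-truthed synthetic L1 larvae: a
#' straightened worm is a rod of `n_cells` nuclei (558 by default) with
#' anterior crowding, per-cell anisotropic positional variability, and a
#' per-animal global affine distortion, optional smooth bending and
#' optional spurious outlier nuclei.
#'
#' @param n_cells number of cells (default 558).
#' @param rod_length anteroposterior length in um (default 250).
#' @param radial_spread dorsoventral/left-right spread in um (default 5).
#' @param sd_range per-axis template SD range in um, cells draw uniformly
#'   from it (default 0.2 to 0.6, calibrated so that annotation of
#'   synthetic worms at 1x noise operates in the accuracy regime the
#'   tool attains on real animals; see the methods vignette).
#' @param noise_multiplier positional noise as a multiple of the per-cell
#'   template SD (default 1).
#' @param rotation_deg max rotation per axis in degrees (default 10).
#' @param scale_range anisotropic scale range (default 0.9 to 1.1).
#' @param shear max shear coefficient (default 0.05).
#' @param translation max translation per axis in um (default 10).
#' @param bend_amplitude quadratic bend amplitude in um along Y (default 0).
#' @param n_outliers spurious uniform nuclei to add (default 0).
#' @param sigma_log lognormal intensity noise SD for expression (default 0.2).
#' @param seed mandatory RNG seed for reproducibility.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 558L, rod_length = 250, radial_spread = 5,
                       sd_range = c(0.2, 0.6), noise_multiplier = 1,
                       rotation_deg = 10, scale_range = c(0.9, 1.1),
                       shear = 0.05, translation = 10, bend_amplitude = 0,
                       n_outliers = 0L, sigma_log = 0.2, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- list(n_cells = as.integer(n_cells), rod_length = rod_length,
              radial_spread = radial_spread, sd_range = sd_range,
              noise_multiplier = noise_multiplier,
              rotation_deg = rotation_deg, scale_range = scale_range,
              shear = shear, translation = translation,
              bend_amplitude = bend_amplitude,
              n_outliers = as.integer(n_outliers),
              sigma_log = sigma_log, seed = as.integer(seed))
  stopifnot(all(vapply(cfg, function(x) all(is.finite(x)), logical(1L))))
  structure(cfg, class = "sim_config")
}

# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a parametric synthetic worm template
#'
#' Cells are placed along an anteroposterior rod with anterior crowding
#' (the head is denser, as in L1 anatomy) and small dorsoventral and
#' left-right offsets; each cell's per-axis positional SD is drawn
#' uniformly from the configured range. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return A `worm_template` with `n_cells` identities `cell_001`, ...
#' @export
make_synthetic_template <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cells < 10L) stop("need at least 10 cells")
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    # u^1.5 crowds positions towards the anterior (x = 0)
    x <- cfg$rod_length * sort(runif(n)^1.5)
    y <- rnorm(n, 0, cfg$radial_spread / 2.5)
    z <- rnorm(n, 0, cfg$radial_spread / 2.5)
    y <- pmin(pmax(y, -cfg$radial_spread), cfg$radial_spread)
    z <- pmin(pmax(z, -cfg$radial_spread), cfg$radial_spread)
    sds <- matrix(runif(3L * n, cfg$sd_range[1L], cfg$sd_range[2L]), n, 3L)
    ids <- sprintf("cell_%03d", seq_len(n))
    worm_template(ids, cbind(x, y, z), sds,
                  provenance = sprintf("synthetic template (seed %d)", cfg$seed))
  })
}

# random affine distortion drawn from the configured ranges
random_affine <- function(cfg) {
  ang <- runif(3L, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3L, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3L, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3L, byrow = TRUE)
  S <- diag(runif(3L, cfg$scale_range[1L], cfg$scale_range[2L]))
  H <- diag(3L)
  H[1L, 2L] <- runif(1L, -cfg$shear, cfg$shear)
  H[2L, 3L] <- runif(1L, -cfg$shear, cfg$shear)
  t <- runif(3L, -cfg$translation, cfg$translation)
  affine3d(cbind(Rz %*% Ry %*% Rx %*% S %*% H, t))
}

#' Simulate a worm from a template with known ground truth
#'
#' Applies per-cell Gaussian jitter (per-axis template SD times the noise
#' multiplier), an optional smooth quadratic bend along the body axis, a
#' random global affine distortion, optional uniform outlier points, and
#' a random point-order permutation. The true assignment and transforms
#' are recorded.
#'
#' @param template a `worm_template`.
#' @param cfg a [sim_config()].
#' @param worm_id identifier for the generated worm.
#' @return A list with `pointset` (a labelled `point_set`; outlier points
#'   carry labels `outlier_*`) and `truth` (list: `assignment` mapping
#'   subject row to template cell index, `NA` for outliers; `affine`;
#'   `displacements`).
#' @export
simulate_worm <- function(template, cfg, worm_id = "sim") {
  stopifnot(inherits(template, "worm_template"), inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    k <- nrow(template$mean)
    jit <- matrix(rnorm(3L * k), k, 3L) * template$sd * cfg$noise_multiplier
    pts <- template$mean + jit
    if (cfg$bend_amplitude != 0) {
      xr <- range(template$mean[, 1L])
      u <- (pts[, 1L] - mean(xr)) / (diff(xr) / 2)
      pts[, 2L] <- pts[, 2L] + cfg$bend_amplitude * u^2
    }
    M <- random_affine(cfg)
    pts <- apply_affine(M, pts)
    assignment <- seq_len(k)
    labels <- template$cell_ids
    if (cfg$n_outliers > 0L) {
      bb <- apply(pts, 2L, range)
      extra <- sapply(1:3, function(a) runif(cfg$n_outliers, bb[1L, a], bb[2L, a]))
      extra <- matrix(extra, ncol = 3L)
      pts <- rbind(pts, extra)
      assignment <- c(assignment, rep(NA_integer_, cfg$n_outliers))
      labels <- c(labels, sprintf("outlier_%02d", seq_len(cfg$n_outliers)))
    }
    perm <- sample.int(nrow(pts))
    ps <- point_set(pts[perm, , drop = FALSE], worm_id = worm_id,
                    labels = labels[perm])
    list(pointset = ps,
         truth = list(assignment = assignment[perm], affine = M,
                      displacements = jit))
  })
}

#' Simulate a labelled training set of worms
#'
#' Convenience wrapper generating `n_worms` independent worms from one
#' template (seeds derived from `cfg$seed`), each fully labelled, as
#' consumed by [build_template()] and friends.
#'
#' @param template a `worm_template`.
#' @param cfg a [sim_config()]; worm `w` uses seed `cfg$seed + w`.
#' @param n_worms number of worms.
#' @return List of labelled `point_set`s.
#' @export
simulate_training_set <- function(template, cfg, n_worms) {
  lapply(seq_len(n_worms), function(w) {
    cfg_w <- cfg
    cfg_w$seed <- cfg$seed + w
    simulate_worm(template, cfg_w, worm_id = sprintf("sim_%03d", w))$pointset
  })
}

#' Simulate reporter measurements realizing specified expression patterns
#'
#' Generates per-nucleus DAPI and reporter intensities for a set of
#' synthetic TFs so that each spatial-pattern detector has positive and
#' negative controls. Expressing nuclei carry a lognormal-noised signal
#' on top of a flat background; non-expressing nuclei and the ten
#' pseudonuclei sit exactly at background, so their quantified level is 0
#' (idealized photometry: signal noise is modelled, background
#' variability is not).
#'
#' @param template a `worm_template` naming the cells.
#' @param patterns list of TF specs, each a list with `name`, `type`
#'   (`"off"`, `"on"`, `"window"`, `"gradient"`, `"founder"`,
#'   `"asymmetric"`), and type-specific fields: `cells` (on/window),
#'   `bundle_cells` + `peak_nf` (gradient: named list bundle -> ordered
#'   cells), `left`/`right` + `n_asym` (asymmetric), `signal_nf`
#'   (normalized-fluorescence amplitude, default 3000).
#' @param cfg a [sim_config()] (supplies `sigma_log` and `seed`).
#' @param n_worms worms per TF (default 8).
#' @param dapi_mean,background mean DAPI and background reporter
#'   intensities (defaults 1000 and 200).
#' @return A list with `measurements` (per TF, a list of per-worm
#'   measurement data frames for [quantify_stack()]) and `truth` (data
#'   frame of TF names and planted pattern types).
#' @export
simulate_expression <- function(template, patterns, cfg, n_worms = 8L,
                                dapi_mean = 1000, background = 200) {
  stopifnot(inherits(template, "worm_template"), inherits(cfg, "sim_config"))
  cells <- template$cell_ids
  for (p in patterns) {
    claimed <- c(p$cells, unlist(p$bundle_cells), p$left, p$right)
    bad <- setdiff(claimed, cells)
    if (length(bad))
      stop("pattern '", p$name, "' names unknown cells: ",
           paste(bad, collapse = ", "))
  }
  with_seed(cfg$seed, {
    out <- list()
    for (p in patterns) {
      amp <- if (is.null(p$signal_nf)) 3000 else p$signal_nf
      worms <- vector("list", n_worms)
      for (w in seq_len(n_worms)) {
        nf <- setNames(numeric(length(cells)), cells)
        if (p$type == "on") nf[p$cells] <- amp
        else if (p$type == "window") nf[p$cells] <- amp
        else if (p$type == "gradient") {
          for (bc in p$bundle_cells) {
            ramp <- seq(0, 1, length.out = length(bc))
            nf[bc] <- ramp * (if (is.null(p$peak_nf)) amp else p$peak_nf)
          }
        } else if (p$type == "founder") nf[p$cells] <- amp
        else if (p$type == "asymmetric") {
          n_asym <- if (is.null(p$n_asym)) n_worms else p$n_asym
          if (w <= n_asym) nf[p$left] <- amp
          else { nf[p$left] <- amp; nf[p$right] <- amp }  # symmetric worm
        }
        dapi <- rlnorm(length(cells), log(dapi_mean), cfg$sigma_log)
        noise <- rlnorm(length(cells), 0, cfg$sigma_log)
        on <- nf > 0
        reporter <- rep(background, length(cells))
        # invert the DAPI normalization so the quantified nf has the
        # planted amplitude (up to the lognormal noise on the signal)
        reporter[on] <- background +
          nf[on] * noise[on] * dapi[on] / dapi_mean
        df <- data.frame(
          worm_id = sprintf("%s_w%02d", p$name, w),
          nucleus_index = c(seq_along(cells),
                            length(cells) + 1:10) - 1L,
          cell_id = c(cells, sprintf("pseudo_%02d", 1:10)),
          dapi = c(dapi, rlnorm(10L, log(dapi_mean), cfg$sigma_log)),
          reporter = c(reporter, rep(background, 10L)),
          is_pseudo = c(rep(FALSE, length(cells)), rep(TRUE, 10L)),
          stringsAsFactors = FALSE)
        worms[[w]] <- df
      }
      out[[p$name]] <- worms
    }
    truth <- data.frame(tf = vapply(patterns, `[[`, character(1L), "name"),
                        pattern = vapply(patterns, `[[`, character(1L), "type"),
                        stringsAsFactors = FALSE)
    list(measurements = out, truth = truth)
  })
}

#' Quantified level matrices from simulated measurements
#'
#' Pipes each simulated stack through [quantify_stack()] and assembles,
#' per TF, a worms x cells level matrix plus the across-worm mean matrix
#' used by the spatial detectors.
#'
#' @param sim output of [simulate_expression()].
#' @return List with `by_worm` (named list of worms x cells matrices) and
#'   `mean_matrix` (TF x cells `expression_matrix`).
#' @export
levels_from_measurements <- function(sim) {
  by_worm <- lapply(sim$measurements, function(worms) {
    t(vapply(worms, quantify_stack,
             numeric(nrow(worms[[1L]]) - sum(worms[[1L]]$is_pseudo))))
  })
  mm <- t(vapply(by_worm, colMeans, numeric(ncol(by_worm[[1L]]))))
  list(by_worm = by_worm,
       mean_matrix = structure(mm, class = c("expression_matrix", "matrix")))
}
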
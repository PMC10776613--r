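test_that("CAC closed forms and the score-matrix cross-check hold", {
  tpl <- tiny_template(k = 20, sd = 0.4)
  alpha <- 20
  pts <- tpl$mean
  pts[4, 1] <- pts[4, 1] + alpha * tpl$sd[4, 1]
  cc <- cac(seq_len(20), pts, tpl, alpha = alpha)
  expect_equal(unname(cc[4]), exp(-0.5))
  expect_true(all(cc[-4] == 1))
  expect_true(all(cc >= 0 & cc <= 1))

  # the CAC vector is the score-matrix diagonal gathered by the assignment
  set.seed(3)
  pts2 <- tpl$mean + matrix(rnorm(60, 0, 2), 20, 3)
  perm <- sample.int(20)
  cc2 <- cac(perm, pts2, tpl, alpha = alpha)
  f <- score_matrix(pts2, tpl, alpha = alpha)
  expect_equal(unname(cc2[perm]), unname(f[cbind(1:20, perm)]),
               tolerance = 1e-12)
})

test_that("WAC averages all per-cell confidences", {
  expect_equal(wac(rep(1, 5)), 1)
  expect_equal(wac(c(1, 0)), 0.5)
  set.seed(1)
  v <- runif(558)
  expect_equal(wac(v), mean(v))
  expect_error(wac(numeric(0)), "empty")
})

test_that("the 0.995 output rule selects modes with an inclusive boundary", {
  tpl <- tiny_template(k = 10, sd = 1)
  mk <- function(mode, target_wac) {
    # place all points at a common Mahalanobis radius giving the target WAC
    r <- sqrt(-2 * log(target_wac))
    pts <- tpl$mean
    pts[, 1] <- pts[, 1] + r * 20 * tpl$sd[, 1]
    worm_annotation(1:10, tpl, pts, mode = mode, worm_id = "w")
  }
  rpm <- mk("rpm", 0.9)
  expect_equal(select_output(rpm, mk("bipartite", 0.996))$mode, "bipartite")
  expect_equal(select_output(rpm, mk("bipartite", 0.990))$mode, "rpm")
  exact <- mk("bipartite", 0.995)
  expect_equal(exact$wac, 0.995, tolerance = 1e-12)
  expect_equal(select_output(rpm, exact)$mode, "bipartite")
})

# construct a validation set with prescribed per-instance CAC and correctness
fake_validation <- function(tpl, cacs, correct, cell = tpl$cell_ids[1]) {
  lapply(seq_along(cacs), function(i) {
    r <- sqrt(-2 * log(cacs[i]))
    pts <- tpl$mean
    pts[1, 1] <- pts[1, 1] + r * 20 * tpl$sd[1, 1]
    ann <- worm_annotation(seq_len(nrow(pts)), tpl, pts, worm_id = "v")
    truth <- tpl$cell_ids
    if (!correct[i]) truth[1] <- "somebody_else"
    list(annotation = ann, truth = truth)
  })
}

test_that("CAC threshold calibration follows the sub-50% accuracy rule", {
  tpl <- tiny_template(k = 6, sd = 0.5)
  # 30 instances: correct iff CAC > 0.9 (both sides populated)
  cacs <- c(seq(0.50, 0.88, length.out = 15), seq(0.91, 0.999, length.out = 15))
  correct <- cacs > 0.9
  calib <- calibrate_cac_thresholds(fake_validation(tpl, cacs, correct),
                                    min_support = 20)
  thr <- calib$threshold[calib$cell_id == tpl$cell_ids[1]]
  expect_lt(abs(thr - 0.9), 0.05)
  # accuracy among instances at or below the threshold is indeed < 50%
  expect_lt(mean(correct[cacs <= thr]), 0.5)

  # an always-correct cell is never flagged
  calib2 <- calibrate_cac_thresholds(
    fake_validation(tpl, cacs, rep(TRUE, 30)), min_support = 20)
  expect_equal(calib2$threshold[calib2$cell_id == tpl$cell_ids[1]], 0)

  # under-supported cells get the default threshold
  calib3 <- calibrate_cac_thresholds(
    fake_validation(tpl, cacs[1:5], rep(FALSE, 5)),
    min_support = 20, default_threshold = 0.25)
  expect_equal(calib3$threshold[calib3$cell_id == tpl$cell_ids[1]], 0.25)
  expect_error(calibrate_cac_thresholds(list()), "empty")
})

test_that("EPC flags exactly the cells below their thresholds", {
  tpl <- tiny_template(k = 8, sd = 0.5)
  set.seed(6)
  pts <- tpl$mean + matrix(rnorm(24, 0, 4), 8, 3)
  ann <- worm_annotation(1:8, tpl, pts, worm_id = "e")
  thresholds <- rep(c(0, 0.999), 4)
  calib <- structure(
    data.frame(cell_id = tpl$cell_ids, threshold = thresholds,
               support = 30L, stringsAsFactors = FALSE),
    default_threshold = 0, class = c("cac_calibration", "data.frame"))
  out <- epc_flag_and_reassign(ann, tpl, calib)
  expect_setequal(out$flagged, tpl$cell_ids[ann$cac < thresholds])
  # no fixes supplied: assignment unchanged
  expect_identical(out$assignment, ann$assignment)
})

test_that("a curated fix on a swapped pair repairs both members", {
  tpl <- tiny_template(k = 8, sd = 0.5)
  # nuclei sit exactly at their true template means, but the annotation
  # swapped cells 1 and 2; truth is the identity labelling
  wrong <- 1:8; wrong[1:2] <- c(2L, 1L)
  ann <- worm_annotation(wrong, tpl, tpl$mean, worm_id = "s")
  truth <- tpl$cell_ids
  expect_equal(annotation_accuracy(ann, truth), 1 - 2 / 8)
  calib <- structure(
    data.frame(cell_id = tpl$cell_ids, threshold = 0, support = 30L,
               stringsAsFactors = FALSE),
    default_threshold = 0, class = c("cac_calibration", "data.frame"))
  fix <- setNames(1L, tpl$cell_ids[1])        # row 1 is truly cell 1
  out <- epc_flag_and_reassign(ann, tpl, calib, curated = fix)
  expect_equal(annotation_accuracy(out, truth), 1)
  expect_error(
    epc_flag_and_reassign(ann, tpl, calib,
                          curated = setNames(c(1L, 1L), tpl$cell_ids[1:2])),
    "injective|conflicting")
})

test_that("accuracy is 1 - errors/k with the template size as denominator", {
  tpl <- tiny_template(k = 10, sd = 0.5)
  ann <- worm_annotation(1:10, tpl, tpl$mean, worm_id = "a")
  truth <- tpl$cell_ids
  expect_equal(annotation_accuracy(ann, truth), 1)
  truth_wrong <- rev(tpl$cell_ids)
  expect_equal(annotation_accuracy(ann, truth_wrong), 0)
  truth3 <- truth; truth3[1:3] <- "x"
  expect_equal(annotation_accuracy(ann, truth3), 1 - 3 / 10)
  # the printed headline: 16.5 mean errors over 558 cells -> 97.0%
  expect_equal(round(100 * (1 - 16.5 / 558), 1), 97.0)
})

test_that("WAC correlates with accuracy across noise levels", {
  tpl <- make_synthetic_template(sim_config(n_cells = 100, seed = 90))
  noise <- rep(c(0.5, 1, 1.5, 2), each = 3)
  res <- t(vapply(seq_along(noise), function(i) {
    sw <- simulate_worm(tpl, sim_config(n_cells = 100, seed = 900 + i,
                                        noise_multiplier = noise[i]), "w")
    both <- annotate_stack(sw$pointset, tpl)
    sel <- select_output(both$rpm, both$bipartite)
    c(sel$wac, annotation_accuracy(sel, sw$pointset$labels))
  }, numeric(2)))
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.5)
})
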
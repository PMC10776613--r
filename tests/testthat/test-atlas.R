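make_training <- function(template, affines, perm_seed = 1) {
  set.seed(perm_seed)
  lapply(seq_along(affines), function(i) {
    k <- nrow(template$mean)
    affine_worm(template, affines[[i]], worm_id = paste0("t", i),
                perm = sample.int(k))
  })
}

test_that("identical worms give zero-variance template floored at sd_floor", {
  tpl <- tiny_template()
  worms <- lapply(1:4, function(i)
    point_set(tpl$mean, worm_id = paste0("w", i), labels = tpl$cell_ids))
  built <- build_template(worms, 1L)
  expect_equal(unname(built$mean), unname(tpl$mean), tolerance = 1e-8)
  expect_true(all(built$sd == built$sd_floor))
})

test_that("template built from affine images recovers the target worm's coordinates", {
  tpl <- tiny_template()
  affines <- c(list(affine_identity()), lapply(2:5, rand_affine))
  worms <- make_training(tpl, affines)
  built <- build_template(worms, 1L)
  # target worm (index 1) is the untransformed template
  expect_equal(unname(built$mean[worms[[1]]$labels, ]),
               unname(worms[[1]]$coords), tolerance = 1e-6)
})

test_that("template SDs equal an independent per-axis sample SD of registered copies", {
  tpl <- tiny_template()
  set.seed(9)
  worms <- lapply(1:6, function(i) {
    pts <- tpl$mean + matrix(rnorm(length(tpl$mean), 0, 0.5),
                             nrow(tpl$mean), 3)
    point_set(pts, worm_id = paste0("w", i), labels = tpl$cell_ids)
  })
  built <- build_template(worms, 1L, sd_floor = 1e-6)
  # independent recomputation: register each worm, stack, per-axis SD
  target <- worms[[1]]
  reg <- lapply(worms, function(ps) {
    idx <- match(target$labels, ps$labels)
    src <- ps$coords[idx, ]
    apply_affine(fit_global_affine(src, target$coords), src)
  })
  for (axis in 1:3) {
    manual <- apply(sapply(reg, function(r) r[, axis]), 1, sd)
    expect_equal(unname(built$sd[target$labels, axis]), unname(manual),
                 tolerance = 1e-8)
  }
})

test_that("a worm missing an identity is rejected", {
  tpl <- tiny_template()
  good <- point_set(tpl$mean, labels = tpl$cell_ids)
  bad <- point_set(tpl$mean[-1, ], labels = tpl$cell_ids[-1])
  expect_error(build_template(list(good, bad), 1L), "vocabulary|missing")
})

test_that("atlas matching score is 1 for coincident worms and counts all per-cell scores", {
  tpl <- tiny_template()
  worms <- lapply(1:3, function(i)
    point_set(tpl$mean, worm_id = paste0("w", i), labels = tpl$cell_ids))
  s <- atlas_matching_score(tpl, worms)
  expect_equal(as.numeric(s), 1, tolerance = 1e-9)
  expect_equal(attr(s, "n_scores"), 3 * length(tpl$cell_ids))
  expect_equal(dim(attr(s, "per_cell")), c(3L, length(tpl$cell_ids)))
})

test_that("a single cell displaced by one SD along X scores exp(-1/2)", {
  tpl <- tiny_template(sd = 0.5)
  pts <- tpl$mean
  pts[5, 1] <- pts[5, 1] + tpl$sd[5, 1]
  # identity registration: use the worm itself as its own affine frame
  delta <- (pts - tpl$mean) / tpl$sd
  f <- exp(-0.5 * rowSums(delta^2))
  expect_equal(unname(f[5]), exp(-0.5))
  expect_true(all(f[-5] == 1))
})

test_that("matching score decreases as a displacement grows", {
  tpl <- tiny_template(sd = 0.5)
  score_at <- function(shift) {
    pts <- tpl$mean
    pts[3, 2] <- pts[3, 2] + shift
    # defeat the global affine refit by displacing a single cell only
    worms <- list(point_set(pts, labels = tpl$cell_ids))
    as.numeric(atlas_matching_score(tpl, worms))
  }
  s <- vapply(c(0.5, 1.0, 2.0), score_at, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("optimal template selection equals exhaustive score comparison", {
  tpl <- tiny_template()
  set.seed(21)
  worms <- c(list(point_set(tpl$mean, worm_id = "w1", labels = tpl$cell_ids)),
             lapply(2:4, function(i) {
               pts <- tpl$mean + matrix(rnorm(length(tpl$mean), 0, 0.8),
                                        nrow(tpl$mean), 3)
               point_set(pts, worm_id = paste0("w", i), labels = tpl$cell_ids)
             }))
  sel <- select_optimal_template(worms)
  expect_true(all(sel$scores > 0 & sel$scores <= 1))

  # exhaustive-comparison oracle: argmax of individually computed scores
  manual <- vapply(1:4, function(i)
    as.numeric(atlas_matching_score(build_template(worms, i), worms)),
    numeric(1))
  expect_equal(sel$index, which.max(manual))
  expect_equal(sel$scores, manual, tolerance = 1e-12)

  # two identical worms: tie broken by the lowest index
  two <- worms[c(1, 1)]
  two[[2]]$worm_id <- "w1b"
  expect_equal(select_optimal_template(two)$index, 1L)
})

test_that("selection is invariant to worm ordering up to the tie-break", {
  tpl <- tiny_template()
  set.seed(22)
  worms <- lapply(1:4, function(i) {
    pts <- tpl$mean + matrix(rnorm(length(tpl$mean), 0, 0.6),
                             nrow(tpl$mean), 3)
    point_set(pts, worm_id = paste0("w", i), labels = tpl$cell_ids)
  })
  sel <- select_optimal_template(worms)
  perm <- c(3, 1, 4, 2)
  sel_p <- select_optimal_template(worms[perm])
  expect_equal(perm[sel_p$index], sel$index)
})

test_that("consensus template is a fixed point for exactly-affine training worms", {
  tpl <- tiny_template()
  worms <- make_training(tpl, lapply(2:5, rand_affine))
  seed_tpl <- build_template(worms, 1L)
  cons <- build_consensus_template(worms, seed_tpl)
  expect_true(attr(cons, "converged"))
  expect_equal(attr(cons, "iterations"), 1L)
  expect_lt(attr(cons, "movement")[1], 1e-6)
})

test_that("symmetric two-worm perturbations cancel in the consensus", {
  # cancellation is exact to first order in delta: the perturbed cell
  # also enters the regressors of the worm-to-template affine fit, so
  # the two registrations differ at O(delta^2)
  tpl <- tiny_template()
  for (delta in c(0.01, 0.1)) {
    p1 <- tpl$mean; p1[7, 2] <- p1[7, 2] + delta
    p2 <- tpl$mean; p2[7, 2] <- p2[7, 2] - delta
    worms <- list(point_set(p1, worm_id = "a", labels = tpl$cell_ids),
                  point_set(p2, worm_id = "b", labels = tpl$cell_ids))
    cons <- build_consensus_template(worms, tpl)
    expect_lt(abs(cons$mean[7, 2] - tpl$mean[7, 2]), delta^2)
  }
})

test_that("consensus movement is recorded and non-increasing after the first step", {
  tpl <- tiny_template()
  set.seed(30)
  worms <- lapply(1:5, function(i) {
    pts <- apply_affine(rand_affine(40 + i),
                        tpl$mean + matrix(rnorm(length(tpl$mean), 0, 0.4),
                                          nrow(tpl$mean), 3))
    point_set(pts, worm_id = paste0("w", i), labels = tpl$cell_ids)
  })
  cons <- build_consensus_template(worms, build_template(worms, 1L),
                                   tol = 1e-4)
  mv <- attr(cons, "movement")
  expect_gt(length(mv), 1L)
  expect_true(all(diff(mv[-1]) <= 1e-9))
})

test_that("template building is equivariant under affine maps of the target", {
  tpl <- tiny_template()
  worms <- make_training(tpl, lapply(2:5, rand_affine))
  built <- build_template(worms, 2L)
  M <- rand_affine(99)
  worms2 <- worms
  worms2[[2]] <- point_set(apply_affine(M, worms[[2]]$coords),
                           worm_id = "t2m", labels = worms[[2]]$labels)
  built2 <- build_template(worms2, 2L)
  expect_equal(unname(built2$mean), unname(apply_affine(M, built$mean)),
               tolerance = 1e-6)
})
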
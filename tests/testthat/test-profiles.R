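# block-structured expression matrix: two disjoint TF programs
block_matrix <- function(n_tf = 20, seed = 5) {
  set.seed(seed)
  cells <- c(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5))
  m <- matrix(abs(rnorm(n_tf * 10, 0, 0.05)), n_tf, 10,
              dimnames = list(sprintf("tf%02d", 1:n_tf), cells))
  m[1:(n_tf / 2), 1:5] <- m[1:(n_tf / 2), 1:5] + 3
  m[(n_tf / 2 + 1):n_tf, 6:10] <- m[(n_tf / 2 + 1):n_tf, 6:10] + 3
  m
}

test_that("identical cells merge at height zero and blocks get full support", {
  m <- block_matrix()
  m <- cbind(m, a01_twin = m[, "a01"])
  set.seed(1)
  dend <- cluster_cells(m, n_boot = 50)
  hc <- dend$hclust
  first <- which(hc$height < 1e-10)[1]
  merged <- sort(hc$labels[-hc$merge[first, ]])
  expect_equal(merged, c("a01", "a01_twin"))

  # the two planted blocks are clades with 100% bootstrap support
  keyA <- sort(c(sprintf("a%02d", 1:5), "a01_twin"))
  keyB <- sort(sprintf("b%02d", 1:5))
  keys <- lapply(dend$leafsets, sort)
  iA <- which(vapply(keys, identical, logical(1), keyA))
  iB <- which(vapply(keys, identical, logical(1), keyB))
  expect_length(iA, 1L); expect_length(iB, 1L)
  expect_equal(dend$support[iA], 100)
  expect_equal(dend$support[iB], 100)
  expect_equal(ncol(dend$bp_table), 10L)   # 0.5 .. 1.4 fraction grid
})

test_that("correlation distance of anticorrelated profiles is 2", {
  x <- seq(-1, 1, length.out = 6)
  m <- rbind(x, -x, x * 2, -x * 0.5)
  colnames(m) <- sprintf("c%d", 1:6)
  d <- 1 - cor(m)
  expect_equal(max(d), 2, tolerance = 1e-12)
})

test_that("constant-profile cells are dropped with a warning", {
  m <- block_matrix()
  m <- cbind(m, flat = rep(1, nrow(m)) * 0)
  set.seed(2)
  expect_warning(dend <- cluster_cells(m, n_boot = 5), "flat")
  expect_false("flat" %in% dend$hclust$labels)
})

test_that("parsimony subtyping matches brute force on a 4-leaf tree", {
  # tree ((A,B),(C,D)) with A,B,D given and C other
  hc <- hclust(dist(c(A = 0, B = 0.1, C = 10, D = 10.1)), method = "average")
  res <- subtype_by_parsimony(hc, c("A", "B", "D"))
  expect_equal(res$inter_type_edges,
               brute_force_parsimony(hc, c("A", "B", "D")))
  # optimum labels every internal node given-type: one bichromatic edge
  # (to leaf C) and a single subtype holding all three given leaves
  expect_equal(res$inter_type_edges, 1L)
  expect_length(res$subtypes, 1L)
  expect_setequal(res$subtypes[[1]], c("A", "B", "D"))
  expect_setequal(res$neighbors[[1]], "C")
})

test_that("all given-type leaves give one subtype and zero inter-type edges", {
  hc <- hclust(dist(1:6), method = "average")
  hc$labels <- sprintf("L%d", 1:6)
  res <- subtype_by_parsimony(hc, hc$labels)
  expect_length(res$subtypes, 1L)
  expect_setequal(res$subtypes[[1]], hc$labels)
  expect_equal(res$inter_type_edges, 0L)
  expect_length(res$neighbors[[1]], 0L)
})

test_that("parsimony edge count equals exhaustive labeling for random trees up to 12 leaves", {
  set.seed(14)
  for (trial in 1:12) {
    n <- sample(4:12, 1)
    hc <- hclust(dist(rnorm(n)), method = "average")
    hc$labels <- sprintf("L%02d", 1:n)
    given <- sample(hc$labels, sample(seq_len(n - 1), 1))
    res <- subtype_by_parsimony(hc, given)
    expect_equal(res$inter_type_edges, brute_force_parsimony(hc, given),
                 info = paste("trial", trial))
    # subtypes partition the given leaves; neighbors are disjoint from them
    expect_setequal(unlist(res$subtypes), given)
    for (i in seq_along(res$subtypes))
      expect_length(intersect(res$subtypes[[i]], res$neighbors[[i]]), 0L)
  }
})

test_that("subtypes on a block matrix find the planted split with its neighbor clade", {
  # nested structure: blocks A and B, each holding a tight sub-pair
  # (a01, a02) and (b01, b02) marked by their own TF programs
  m <- block_matrix()
  extra <- matrix(0, 8, 10, dimnames = list(sprintf("sub%02d", 1:8),
                                            colnames(m)))
  extra[1:4, c("a01", "a02")] <- 4
  extra[5:8, c("b01", "b02")] <- 4
  m <- rbind(m, extra)
  set.seed(3)
  dend <- cluster_cells(m, n_boot = 5)
  # "type" = a01,a02 + b01,b02: two clades separated by the block gap
  res <- subtype_by_parsimony(dend, c("a01", "a02", "b01", "b02"))
  expect_length(res$subtypes, 2L)
  sizes <- sort(vapply(res$subtypes, length, integer(1)))
  expect_equal(sizes, c(2L, 2L))
  # neighbor clades come from the same block as each subtype
  for (i in seq_along(res$subtypes)) {
    blk <- substr(res$subtypes[[i]][1], 1, 1)
    expect_true(all(substr(res$neighbors[[i]], 1, 1) == blk))
  }
})

test_that("JSD matches the direct formula and its bounds", {
  # identical distributions: zero divergence
  m <- matrix(c(0.3, 0.3, 0.7, 0.7), 2, 2,
              dimnames = list(c("t1", "t2"), c("x", "y")))
  expect_equal(group_jsd(m, "x", "y"), 0, tolerance = 1e-12)
  # disjoint supports: maximal divergence 1 (base-2)
  m2 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("t1", "t2"), c("x", "y")))
  expect_equal(group_jsd(m2, "x", "y"), 1, tolerance = 1e-12)
  # p = (1,0) vs q = (0.5,0.5): ~0.3113
  m3 <- matrix(c(1, 0, 0.5, 0.5), 2, 2,
               dimnames = list(c("t1", "t2"), c("x", "y")))
  expect_equal(group_jsd(m3, "x", "y"), 0.311278, tolerance = 1e-5)
  expect_equal(group_jsd(m3, "x", "y"),
               direct_jsd(c(1, 0), c(0.5, 0.5)), tolerance = 1e-12)
})

test_that("JSD is symmetric, bounded, and zero only for equal distributions", {
  set.seed(8)
  m <- matrix(abs(rnorm(40)), 8, 5,
              dimnames = list(sprintf("t%d", 1:8), sprintf("c%d", 1:5)))
  for (pair in list(c("c1", "c2"), c("c3", "c4"), c("c1", "c5"))) {
    a <- group_jsd(m, pair[1], pair[2])
    b <- group_jsd(m, pair[2], pair[1])
    expect_equal(a, b, tolerance = 1e-12)
    expect_gte(a, 0); expect_lte(a, 1)
    expect_gt(a, 0)   # random profiles differ
  }
  # all-zero cells fall back to the uniform distribution
  mz <- cbind(m, z1 = 0, z2 = 0)
  expect_equal(group_jsd(mz, "z1", "z2"), 0, tolerance = 1e-12)
})

test_that("normalized subtype JSD behaves as a ratio with a degenerate guard", {
  m <- block_matrix()
  s1 <- c("a01", "a02"); s2 <- c("a03", "a04")
  n1 <- c("b01", "b02"); n2 <- c("b03", "b04")
  # subtypes nearly identical, neighbors far: ratio << 1
  r <- normalized_subtype_jsd(m, s1, s2, n1, n2)
  expect_lt(r, 0.5)
  # ratio of equal JSDs is 1: symmetric construction across the blocks
  r2 <- normalized_subtype_jsd(m, s1, n1, s2, n2)
  expect_equal(r2, 1, tolerance = 0.2)
  # identical groups: denominator degenerates
  mm <- m[, c("a01", "a02", "a03", "a04")]
  colnames(mm) <- c("g1", "g2", "g3", "g4")
  mm[, 2:4] <- mm[, 1]
  expect_error(normalized_subtype_jsd(mm, "g1", "g2", "g3", "g4"),
               "undefined")
})

test_that("the exact Fisher test matches enumeration and the stats oracle", {
  set.seed(10)
  for (trial in 1:40) {
    n <- sample(8:50, 1)
    a <- sample(0:min(20, n - 3), 1)
    tab <- matrix(c(a, sample(0:15, 1), sample(0:15, 1), n), 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, enumerate_fisher(tab), tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})
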
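# Fixtures and independent oracles used across the suite.

# small deterministic template built directly (not via the generator)
tiny_template <- function(k = 24, seed = 42, sd = 0.3) {
  set.seed(seed)
  coords <- cbind(seq(0, 50, length.out = k),
                  rnorm(k, 0, 2), rnorm(k, 0, 2))
  worm_template(sprintf("c%02d", seq_len(k)), coords,
                matrix(sd, k, 3))
}

# labelled point set that is an exact affine image of a template
affine_worm <- function(template, M, worm_id = "aw", perm = NULL) {
  k <- nrow(template$mean)
  if (is.null(perm)) perm <- seq_len(k)
  pts <- apply_affine(M, template$mean)[perm, , drop = FALSE]
  point_set(pts, worm_id = worm_id, labels = template$cell_ids[perm])
}

rand_affine <- function(seed, scale = 0.2) {
  set.seed(seed)
  repeat {
    A <- diag(3) + matrix(rnorm(9, 0, scale), 3, 3)
    if (abs(det(A)) > 0.1) break
  }
  affine3d(cbind(A, rnorm(3, 0, 5)))
}

# brute-force maximum-score assignment over all permutations (k <= 8)
brute_force_assign <- function(scores) {
  k <- nrow(scores)
  perms <- gtools_permutations(k)
  best <- -Inf; best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    tot <- sum(scores[cbind(seq_len(k), p)])
    if (tot > best + 1e-12) { best <- tot; best_p <- p }
  }
  list(assignment = best_p, total = best)
}

# all permutations of 1..n without external packages
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force minimum bichromatic edge count over all internal labelings
brute_force_parsimony <- function(hc, given) {
  n <- length(hc$labels)
  leaf_state <- as.integer(hc$labels %in% given)
  n_int <- n - 1L
  parent <- integer(2L * n - 1L)
  kids <- matrix(0L, n_int, 2L)
  for (i in seq_len(n_int)) {
    ch <- ifelse(hc$merge[i, ] < 0, -hc$merge[i, ], hc$merge[i, ] + n)
    kids[i, ] <- ch
    parent[ch] <- n + i
  }
  best <- Inf
  for (mask in 0:(2^n_int - 1L)) {
    state <- c(leaf_state, as.integer(bitwAnd(bitwShiftR(mask, 0:(n_int - 1L)), 1L)))
    cost <- 0L
    for (v in seq_len(2L * n - 2L))
      if (parent[v] && state[v] != state[parent[v]]) cost <- cost + 1L
    if (cost < best) best <- cost
  }
  best
}

# direct JSD formula on two probability vectors, base 2
direct_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  (kl(p, m) + kl(q, m)) / 2
}

# two-sided Fisher p by full enumeration of tables with fixed margins
enumerate_fisher <- function(tab) {
  K <- sum(tab[1, ]); N <- sum(tab); kk <- sum(tab[, 1])
  lo <- max(0, kk - (N - K)); hi <- min(kk, K)
  probs <- vapply(lo:hi, function(a) {
    choose(K, a) * choose(N - K, kk - a) / choose(N, kk)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# standard muscle-layout fixture: 4 bundles x 12 ranks, founders mixed
muscle_fixture <- function(n_rank = 12L) {
  bundles <- c("DL", "DR", "VL", "VR")
  df <- expand.grid(rank = seq_len(n_rank), bundle = bundles,
                    stringsAsFactors = FALSE)
  df$cell_id <- sprintf("BWM%s%02d", df$bundle, df$rank)
  # stagger founders across ranks and bundles so each founder group spans
  # the whole anteroposterior axis (as MS/C/D muscles do in the animal)
  df$founder <- c("MS", "C", "D")[
    ((df$rank + match(df$bundle, bundles)) %% 3L) + 1L]
  df$founder[1L] <- "AB"
  muscle_layout(df[, c("cell_id", "bundle", "rank", "founder")])
}
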
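# Independent brute-force oracles and small fixtures used across tests.
# Each oracle is written from the definition, not from the implementation
# it checks.

# Tie-aware Spearman: rank each vector (average ranks), then Pearson.
brute_spearman_dissimilarity <- function(Y) {
  n <- nrow(Y)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ri <- rank(Y[i, ], ties.method = "average")
      rj <- rank(Y[j, ], ties.method = "average")
      d[i, j] <- 1 - sum((ri - mean(ri)) * (rj - mean(rj))) /
        sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
    }
  }
  d
}

# Benjamini-Hochberg step-up from the definition: for each i (sorted),
# adj p_(i) = min_{j >= i} min(1, m * p_(j) / j).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Box's epsilon by explicit element sums (no eigendecomposition).
brute_gg_box <- function(V) {
  k <- nrow(V)
  vbar_dd <- mean(diag(V))
  vbar <- mean(V)
  vbar_i <- rowMeans(V)
  num <- k^2 * (vbar_dd - vbar)^2
  den <- (k - 1) * (sum(V^2) - 2 * k * sum(vbar_i^2) + k^2 * vbar^2)
  num / den
}

# Partial correlation as the correlation of residuals from simple linear
# regressions on z.
brute_partial_cor <- function(x, y, z) {
  cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
}

# Grid counting by checking every point against every field.
brute_count <- function(section, fovs) {
  pts <- section$points
  counts <- setNames(integer(length(copath:::HISTO_CLASSES)),
                     copath:::HISTO_CLASSES)
  if (!nrow(pts) || !nrow(fovs)) return(counts)
  fov <- fovs$fov_um[1]
  for (p in seq_len(nrow(pts))) {
    for (f in seq_len(nrow(fovs))) {
      if (pts$x_um[p] >= fovs$x0_um[f] &&
          pts$x_um[p] < fovs$x0_um[f] + fov &&
          pts$y_um[p] >= fovs$y0_um[f] &&
          pts$y_um[p] < fovs$y0_um[f] + fov) {
        counts[pts$class[p]] <- counts[pts$class[p]] + 1L
        break
      }
    }
  }
  counts
}

random_spd <- function(k) {
  A <- matrix(rnorm(k * (k + 2)), k + 2, k)
  crossprod(A) / (k + 2)
}

# Two-group null cohort (no planted structure) at chosen size.
null_cohort <- function(n = 10, R = 83, seed = 1) {
  cfg <- synthetic_config(
    n_per_group = c(groupA = n, groupB = n), R = R,
    group_mode_weights = list(groupA = c(0, 0, 0),
                              groupB = c(0, 0, 0)),
    seed = seed)
  generate_cohort(cfg)
}

# Two-group cohort with distinct planted spatial modes (temporal-like vs
# frontal-like), emulating the svPPA-vs-nfvPPA contrast.
pair_cohort <- function(n = 10, R = 83, seed = 1) {
  cfg <- synthetic_config(n_per_group = c(svPPA = n, nfvPPA = n),
                          R = R, seed = seed)
  generate_cohort(cfg)
}
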
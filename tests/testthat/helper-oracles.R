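# Independent oracles used across the test files. These deliberately use
# naive formulations (double loops, closed forms) so they share no code
# with the implementation they check.

# Fresnel amplitude coefficient at a single interface.
fresnel_r <- function(n1, n2, pol = "s", cos1 = 1, cos2 = 1) {
  if (pol == "s") (n1 * cos1 - n2 * cos2) / (n1 * cos1 + n2 * cos2)
  else (n2 * cos1 - n1 * cos2) / (n2 * cos1 + n1 * cos2)
}

# Airy two-interface reflectance of a single layer at normal incidence.
airy_reflectance <- function(n0, n1, n2, d, lambda) {
  r01 <- fresnel_r(n0, n1)
  r12 <- fresnel_r(n1, n2)
  beta <- 2 * pi * n1 * d / lambda
  r <- (r01 + r12 * exp(-2i * beta)) / (1 + r01 * r12 * exp(-2i * beta))
  Mod(r)^2
}

# Brute-force product-Gaussian KDE evaluated by triple loop over nodes and
# an inner loop over points.
brute_kde <- function(pts, bw, axes) {
  n1 <- length(axes[[1]]); n2 <- length(axes[[2]]); n3 <- length(axes[[3]])
  out <- array(0, dim = c(n1, n2, n3))
  for (i in seq_len(n1)) for (j in seq_len(n2)) for (k in seq_len(n3)) {
    s <- 0
    for (p in seq_len(nrow(pts))) {
      s <- s + dnorm(axes[[1]][i], pts[p, 1], bw[1]) *
               dnorm(axes[[2]][j], pts[p, 2], bw[2]) *
               dnorm(axes[[3]][k], pts[p, 3], bw[3])
    }
    out[i, j, k] <- s / nrow(pts)
  }
  out
}

# Exhaustive bidirectional Chamfer distance in original units via the
# same normalization convention, all pairwise distances by double loop.
brute_chamfer <- function(A, B) {
  lo <- pmin(apply(A, 2, min), apply(B, 2, min))
  hi <- pmax(apply(A, 2, max), apply(B, 2, max))
  rng <- hi - lo
  keep <- which(rng > 0)
  nn_dir <- function(X, Y) {
    mean(sapply(seq_len(nrow(X)), function(i) {
      min(sapply(seq_len(nrow(Y)), function(j) {
        sqrt(sum(((X[i, keep] - Y[j, keep]) / rng[keep])^2))
      }))
    }))
  }
  0.5 * (nn_dir(A, B) + nn_dir(B, A)) * sqrt(mean(rng[keep]^2))
}

# Mann-Whitney pairwise AUC with ties counted one half.
brute_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  s <- 0
  for (a in sp) for (b in sn)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(sp) * length(sn))
}

# All-threshold ROC points by brute force (every cutoff between distinct
# scores plus the extremes).
brute_roc_points <- function(scores, pos) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  t(sapply(cuts, function(ct) {
    called <- scores >= ct
    c(fpr = sum(called & !pos) / sum(!pos),
      tpr = sum(called & pos) / sum(pos))
  }))
}

# Small Gaussian CIELAB-like cloud.
gauss_cloud <- function(n, center, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab_cloud(cbind(rnorm(n, center[1], sd),
                  rnorm(n, center[2], sd),
                  rnorm(n, center[3], sd)))
}
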
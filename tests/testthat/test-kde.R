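test_that("KDE matches the brute-force double-loop oracle", {
  set.seed(2)
  pts <- cbind(runif(10, 40, 60), runif(10, -10, 10), runif(10, 0, 20))
  bw <- c(2, 3, 2.5)
  axes <- list(L = seq(30, 70, length.out = 7),
               a = seq(-20, 20, length.out = 6),
               b = seq(-10, 30, length.out = 5))
  d <- kde_density(lab_cloud(pts), bandwidth = bw, axes = axes)
  expect_equal(d$values, brute_kde(pts, bw, axes), tolerance = 1e-10)
})

test_that("KDE integrates to ~1 and peaks at a lone point", {
  cloud <- gauss_cloud(200, c(50, 0, 0), sd = 2, seed = 4)
  d <- kde_density(cloud, gridsize = 32)
  mass <- sum(d$values) * d$cell_volume
  expect_gte(mass, 0.98)
  expect_lte(mass, 1.005)
  single <- lab_cloud(matrix(c(50, 5, -3), 1))
  ds <- kde_density(single, bandwidth = c(2, 2, 2), gridsize = 16)
  peak <- which(ds$values == max(ds$values), arr.ind = TRUE)[1, ]
  nearest <- sapply(1:3, function(k)
    which.min(abs(ds$axes[[k]] - c(50, 5, -3)[k])))
  expect_equal(unname(peak), unname(nearest))
})

test_that("KDE input validation", {
  cloud <- gauss_cloud(20, c(50, 0, 0), seed = 6)
  expect_error(kde_density(cloud, bandwidth = 0), "bandwidth")
  expect_error(lab_cloud(matrix(numeric(0), 0, 3)), "empty")
})

test_that("IoU is exactly 1 on itself and symmetric in [0, 1]", {
  cloud <- gauss_cloud(300, c(50, 10, -10), sd = 3, seed = 9)
  d <- kde_density(cloud, gridsize = 24)
  expect_identical(kde_iou(d, d), 1)
  other <- gauss_cloud(300, c(55, 12, -6), sd = 3, seed = 10)
  axes <- kde_axes(list(cloud, other), gridsize = 24)
  d1 <- kde_density(cloud, axes = axes)
  d2 <- kde_density(other, axes = axes)
  v <- kde_iou(d1, d2)
  expect_equal(v, kde_iou(d2, d1))
  expect_gt(v, 0); expect_lt(v, 1)
})

test_that("far-separated clouds have IoU below 1e-6", {
  a <- gauss_cloud(200, c(20, 0, 0), sd = 1, seed = 12)
  b <- gauss_cloud(200, c(80, 0, 0), sd = 1, seed = 13)  # 60 sigma apart
  axes <- kde_axes(list(a, b), bandwidth = c(1, 1, 1), gridsize = 48)
  da <- kde_density(a, bandwidth = c(1, 1, 1), axes = axes)
  db <- kde_density(b, bandwidth = c(1, 1, 1), axes = axes)
  expect_lt(kde_iou(da, db), 1e-6)
})

test_that("grids on different axes are refused; all-zero grids undefined", {
  a <- gauss_cloud(50, c(50, 0, 0), seed = 14)
  d1 <- kde_density(a, gridsize = 16)
  d2 <- kde_density(a, gridsize = 17)
  expect_error(kde_iou(d1, d2), "axes")
  z <- d1; z$values[] <- 0
  expect_error(kde_iou(z, z), "undefined")
})

test_that("IoU of offset Gaussians matches the analytic-density quadrature", {
  # two unit-sigma kernels: compare against min/max integral of the exact
  # analytic KDE mixture densities on a fine quadrature grid
  set.seed(15)
  a_pts <- cbind(rnorm(40, 50), rnorm(40, 0), rnorm(40, 0))
  b_pts <- cbind(rnorm(40, 53), rnorm(40, 0), rnorm(40, 0))
  bw <- c(1, 1, 1)
  axes <- kde_axes(list(lab_cloud(a_pts), lab_cloud(b_pts)),
                   bandwidth = bw, gridsize = 40)
  da <- kde_density(lab_cloud(a_pts), bandwidth = bw, axes = axes)
  db <- kde_density(lab_cloud(b_pts), bandwidth = bw, axes = axes)
  got <- kde_iou(da, db)
  # independent fine-grid quadrature of the same analytic mixtures
  fine <- lapply(1:3, function(k)
    seq(min(axes[[k]]), max(axes[[k]]), length.out = 64))
  mix <- function(pts, g) {
    f <- function(x, mu) dnorm(x, mu)
    arr <- array(0, dim = sapply(fine, length))
    for (p in seq_len(nrow(pts))) {
      arr <- arr + outer(outer(f(fine[[1]], pts[p, 1]),
                               f(fine[[2]], pts[p, 2])),
                         f(fine[[3]], pts[p, 3]))
    }
    arr / nrow(pts)
  }
  pa <- mix(a_pts); pb <- mix(b_pts)
  want <- sum(pmin(pa, pb)) / sum(pmax(pa, pb))
  expect_equal(got, want, tolerance = 0.02)
})

test_that("IoU decreases as two synthetic clouds separate", {
  seps <- c(0, 2, 5, 10)
  ious <- sapply(seps, function(s) {
    a <- gauss_cloud(250, c(50, 0, 0), sd = 2, seed = 16)
    b <- gauss_cloud(250, c(50 + s, 0, 0), sd = 2, seed = 17)
    axes <- kde_axes(list(a, b), bandwidth = c(1, 1, 1), gridsize = 32)
    kde_iou(kde_density(a, bandwidth = c(1, 1, 1), axes = axes),
            kde_density(b, bandwidth = c(1, 1, 1), axes = axes))
  })
  expect_true(all(diff(ious) < 0))
})

test_that("Frobenius difference matches the element-wise loop oracle", {
  set.seed(18)
  A <- array(runif(4 * 3 * 5), c(4, 3, 5))
  B <- array(runif(4 * 3 * 5), c(4, 3, 5))
  loop <- 0
  for (i in 1:4) for (j in 1:3) for (k in 1:5)
    loop <- loop + (A[i, j, k] - B[i, j, k])^2
  expect_equal(frobenius_diff(A, B), sqrt(loop), tolerance = 1e-12)
  expect_equal(frobenius_diff(A, A), 0)
  # single-element difference of magnitude d
  B2 <- A; B2[2, 2, 2] <- A[2, 2, 2] + 0.37
  expect_equal(frobenius_diff(A, B2), 0.37, tolerance = 1e-12)
  expect_error(frobenius_diff(A, array(0, c(4, 3, 4))), "dimensions")
})
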
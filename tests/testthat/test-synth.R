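make_spec <- function(...) section_spec(width = 64, height = 48, ...)

test_that("zero-sd fields are exactly the class means and deterministic", {
  spec <- make_spec(ri_healthy = c(1.27, 0), ri_cancer = c(1.37, 0),
                    thickness_um = c(0.5, 0))
  f <- sample_fields(spec, seed = 3)
  expect_equal(unique(f$ri[spec$region_map == 1]), 1.27)
  expect_equal(unique(f$ri[spec$region_map == 2]), 1.37)
  expect_equal(unique(f$thickness_nm[spec$region_map > 0]), 500)
  expect_equal(unique(f$ri[spec$region_map == 0]), numeric(0))
  f2 <- sample_fields(spec, seed = 3)
  expect_identical(f, f2)
})

test_that("class-mean refractive index is recovered within 3 SE at 1e4 pixels", {
  # independent pixels: the plain standard error applies
  spec <- section_spec(width = 200, height = 100, smooth_sigma_px = 0)
  f <- sample_fields(spec, seed = 11)
  healthy <- f$ri[spec$region_map == 1]
  expect_gte(length(healthy), 1e4)
  se <- sd(healthy) / sqrt(length(healthy))
  expect_lt(abs(mean(healthy) - 1.27), 3 * se)
  cancer <- f$ri[spec$region_map == 2]
  expect_lt(abs(mean(cancer) - 1.37), 3 * sd(cancer) / sqrt(length(cancer)))
  # correlated field: same check with the design-effect-corrected SE
  # (Gaussian texture of sigma px has correlation area ~ 4 pi sigma^2)
  spec_c <- section_spec(width = 200, height = 100)
  fc <- sample_fields(spec_c, seed = 11)
  hc <- fc$ri[spec_c$region_map == 1]
  n_eff <- length(hc) / (4 * pi * spec_c$smooth_sigma_px^2)
  expect_lt(abs(mean(hc) - 1.27), 3 * sd(hc) / sqrt(n_eff))
})

test_that("marginals survive spatial correlation", {
  spec <- section_spec(width = 200, height = 100, smooth_sigma_px = 3,
                       thickness_um = c(0.3, 1), thickness_dist = "uniform")
  f <- sample_fields(spec, seed = 12)
  th <- f$thickness_nm[spec$region_map > 0] / 1000
  expect_lt(abs(mean(th) - 0.65), 0.02)
  expect_lt(max(abs(quantile(th, c(0.25, 0.75)) - c(0.475, 0.825))), 0.03)
  ri <- f$ri[spec$region_map == 1]
  expect_lt(abs(sd(ri) - 0.02), 0.003)
})

test_that("constant fields render to the exact forward color within LUT error", {
  spec <- make_spec(ri_healthy = c(1.27, 0), ri_cancer = c(1.37, 0),
                    thickness_um = c(0.5, 0), noise_sd = 0)
  lut <- build_color_lut(spec, n_nodes = 32, d_nodes = 8,
                         d_range_nm = c(450, 550))
  sec <- render_section(spec, lut = lut, seed = 5)
  exact <- simulate_slide_color(1.27, 500, spec$slide)$srgb
  got <- sec$rgb[10, 10, ]
  expect_lt(max(abs(got - exact)), 0.02)
  # LUT error metadata is a delta-E scalar
  expect_true(is.finite(sec$lut_delta_e))
})

test_that("healthy and cancerous regions render to different mean colors,
           and the glass proxy weakens that contrast", {
  spec <- make_spec(noise_sd = 0)
  lut <- build_color_lut(spec, n_nodes = 32, d_nodes = 16)
  sec <- render_section(spec, lut = lut, seed = 6)
  mean_lab <- function(cls) {
    idx <- which(spec$region_map == cls, arr.ind = TRUE)
    rgbm <- cbind(sec$rgb[, , 1][idx], sec$rgb[, , 2][idx], sec$rgb[, , 3][idx])
    colMeans(noscolor:::srgb_matrix_to_lab(rgbm))
  }
  gap_nos <- sqrt(sum((mean_lab(1) - mean_lab(2))^2))
  expect_gt(gap_nos, 5)
  gspec <- make_spec(noise_sd = 0, mode = "glass")
  glut <- build_color_lut(gspec, n_nodes = 32, d_nodes = 16)
  gsec <- render_section(gspec, lut = glut, seed = 6)
  sec <- gsec
  gap_glass <- sqrt(sum((mean_lab(1) - mean_lab(2))^2))
  expect_gt(gap_nos, gap_glass)
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- make_spec()
  lut <- build_color_lut(spec, n_nodes = 16, d_nodes = 16)
  a <- render_section(spec, lut = lut, seed = 9)
  b <- render_section(spec, lut = lut, seed = 9)
  expect_identical(a$rgb, b$rgb)
  c <- render_section(spec, lut = lut, seed = 10)
  expect_false(identical(a$rgb, c$rgb))
})

test_that("labeled tiles are balanced, class-pure and subject-disjoint", {
  spec <- section_spec(width = 120, height = 80)
  lut <- build_color_lut(spec, n_nodes = 16, d_nodes = 16)
  ds <- make_labeled_tiles(spec, n_per_class = 6, tile_px = 16,
                           n_subjects = 2, seed = 2, lut = lut)
  for (split in ds) {
    expect_equal(as.vector(table(split$labels)), c(6, 6))
    expect_true(all(vapply(split$tiles, function(t)
      all(dim(t) == c(16, 16, 3)), logical(1))))
  }
  expect_length(intersect(unique(ds$train$subjects),
                          unique(ds$test$subjects)), 0)
  empty <- make_labeled_tiles(spec, n_per_class = 0, tile_px = 16, lut = lut)
  expect_length(empty$train$tiles, 0)
  # requesting more tiles than the geometry can hold fails loudly
  expect_error(make_labeled_tiles(spec, n_per_class = 500, tile_px = 16,
                                  n_subjects = 1, seed = 2, lut = lut),
               "capacity")
})

test_that("simulated raters reproduce the agreement extremes", {
  truth <- factor(rep(c("healthy", "cancerous", "nonepithelial"), 400))
  perfect <- simulate_raters(truth, 0, seed = 1)
  expect_identical(perfect$rater1, truth)
  k <- cohens_kappa(confusion_matrix(as.character(perfect$rater1),
                                     as.character(perfect$rater2)))
  expect_equal(k$kappa, 1)
  again <- simulate_raters(truth, 0.3, seed = 7)
  again2 <- simulate_raters(truth, 0.3, seed = 7)
  expect_identical(again, again2)
  # rows must be distributions
  expect_error(simulate_raters(truth, matrix(1, 3, 3)), "summing to 1")
})

test_that("truth-blind raters agree only at chance level", {
  truth <- factor(sample(c("healthy", "cancerous", "nonepithelial"),
                         10000, replace = TRUE))
  blind <- matrix(1 / 3, 3, 3)
  rr <- simulate_raters(truth, blind, seed = 15)
  k <- cohens_kappa(confusion_matrix(as.character(rr$rater1),
                                     as.character(rr$rater2)))
  expect_lt(abs(k$kappa), 0.03)
})

test_that("the baseline classifier retrieves training centroids", {
  spec <- section_spec(width = 120, height = 80, noise_sd = 0.005)
  lut <- build_color_lut(spec, n_nodes = 16, d_nodes = 16)
  ds <- make_labeled_tiles(spec, n_per_class = 8, tile_px = 16,
                           n_subjects = 2, seed = 4, lut = lut)
  scores <- baseline_tile_classifier(ds$train$tiles, ds$train$labels,
                                     ds$train$tiles)
  # training tiles must score on the correct side of 0.5
  expect_gt(mean(scores[ds$train$labels == "cancerous"]), 0.5)
  expect_lt(mean(scores[ds$train$labels == "healthy"]), 0.5)
  expect_error(baseline_tile_classifier(ds$train$tiles,
                                        factor(rep("healthy", 16),
                                               levels = levels(ds$train$labels)),
                                        ds$train$tiles), "both classes")
})

test_that("section image and truth fields round-trip through files", {
  spec <- make_spec()
  lut <- build_color_lut(spec, n_nodes = 16, d_nodes = 16)
  sec <- render_section(spec, lut = lut, seed = 20)
  fp <- tempfile(fileext = ".tiff"); fc <- tempfile(fileext = ".csv")
  write_section(sec, fp, fields_csv = fc)
  back <- tiff::readTIFF(fp)
  expect_equal(dim(back), dim(sec$rgb))
  expect_lt(max(abs(back - sec$rgb)), 0.01)
  man <- read.csv(fc)
  expect_equal(nrow(man), 64 * 48)
  expect_equal(man$ri[man$row == 1 & man$col == 1],
               sec$fields$ri[1, 1], tolerance = 1e-6)
  file.remove(fp, fc)
})
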
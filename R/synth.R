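# Synthetic tissue sections: seeded refractive-index and thickness fields
# per class, rendered to RGB through the slide's optical forward model.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Synthetic section specification
#'
#' Describes a synthetic tissue section: image geometry, a per-pixel class
#' map (background / healthy / cancerous), the per-class refractive-index
#' and thickness models, the slide configuration and the sensor noise.
#' Defaults encode the study conditions: healthy RI clustered at 1.27,
#' cancerous at 1.37 (sd 0.02, truncated to \[1.0, 1.6\]), thickness
#' uniform in 0.3-1 um, green (111 nm) slide, 0.01 sRGB sensor noise.
#'
#' @param width,height image size in pixels.
#' @param region_map optional integer matrix (height x width) with values
#'   0 = background, 1 = healthy, 2 = cancerous; default: left half
#'   healthy, right half cancerous.
#' @param ri_healthy,ri_cancer `c(mean, sd)` of the class refractive
#'   index (the marginal per-pixel sd is preserved exactly even when the
#'   field is spatially correlated).
#' @param ri_limits truncation bounds of the RI draws.
#' @param thickness_um two numbers describing the per-pixel tissue
#'   thickness (um): `c(mean, sd)` when `thickness_dist = "normal"` (the
#'   default, one section at a nominal thickness with local
#'   surface-roughness texture), or `c(min, max)` when `thickness_dist =
#'   "uniform"` (marginal exactly uniform; spans the across-section
#'   population range). Dewaxed nominal-2-um sections measure 0.3-1 um
#'   across sections; the default emulates one section at the 0.5 um
#'   condition.
#' @param thickness_dist `"normal"` or `"uniform"` (see `thickness_um`).
#' @param smooth_sigma_px correlation length (Gaussian sigma, pixels) of
#'   the spatial texture fields; 0 gives independent pixels.
#' @param noise_sd additive Gaussian sensor noise sd in sRGB units.
#' @param mode `"nos"` (slide forward model) or `"glass"` (weak-contrast
#'   proxy, see [simulate_glass_color()]).
#' @param slide a [slide_config()].
#' @return Object of class `section_spec`.
#' @export
section_spec <- function(width = 192, height = 128, region_map = NULL,
                         ri_healthy = c(1.27, 0.02),
                         ri_cancer = c(1.37, 0.02),
                         ri_limits = c(1.0, 1.6),
                         thickness_um = c(0.5, 0.02),
                         thickness_dist = c("normal", "uniform"),
                         smooth_sigma_px = 1.5,
                         noise_sd = 0.01,
                         mode = c("nos", "glass"),
                         slide = slide_config()) {
  mode <- match.arg(mode)
  thickness_dist <- match.arg(thickness_dist)
  if (is.null(region_map)) {
    region_map <- matrix(2L, height, width)
    region_map[, seq_len(floor(width / 2))] <- 1L
  }
  region_map <- matrix(as.integer(region_map), nrow(region_map), ncol(region_map))
  if (!all(region_map %in% 0:2))
    stop("region_map values must be 0 (background), 1 (healthy) or 2 (cancerous)")
  if (nrow(region_map) != height || ncol(region_map) != width)
    stop("region_map must be height x width")
  for (p in list(ri_healthy, ri_cancer))
    if (length(p) != 2 || p[1] <= 0 || p[2] < 0) stop("RI model must be c(mean >= 0, sd >= 0)")
  if (thickness_dist == "uniform") {
    if (thickness_um[1] < 0 || thickness_um[2] < thickness_um[1])
      stop("uniform thickness_um must be c(min, max) with 0 <= min <= max")
  } else {
    if (thickness_um[1] <= 0 || thickness_um[2] < 0)
      stop("normal thickness_um must be c(mean > 0, sd >= 0)")
  }
  structure(list(width = width, height = height, region_map = region_map,
                 ri_healthy = ri_healthy, ri_cancer = ri_cancer,
                 ri_limits = ri_limits, thickness_um = thickness_um,
                 thickness_dist = thickness_dist,
                 smooth_sigma_px = smooth_sigma_px, noise_sd = noise_sd,
                 mode = mode, slide = slide),
            class = "section_spec")
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf(
    "<section_spec> %d x %d px, %s mode, RI %.2f/%.2f (sd %.3g), thickness %s(%.3g, %.3g) um\n",
    x$height, x$width, x$mode, x$ri_healthy[1], x$ri_cancer[1],
    x$ri_healthy[2], x$thickness_dist, x$thickness_um[1], x$thickness_um[2]))
  invisible(x)
}

# Thickness extent (nm) covered by a spec's field draws.
thickness_range_nm <- function(spec) {
  if (spec$thickness_dist == "uniform") spec$thickness_um * 1000
  else c(max(spec$thickness_um[1] - 4 * spec$thickness_um[2], 0.05),
         spec$thickness_um[1] + 4 * spec$thickness_um[2]) * 1000
}

# Separable Gaussian blur with edge renormalization.
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  ker <- stats::dnorm(-r:r, sd = sigma)
  ker <- ker / sum(ker)
  blur1 <- function(m) {
    # convolve columns of m with ker, renormalizing truncated edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m)); wsum <- numeric(n)
    for (o in -r:r) {
      w <- ker[o + r + 1]
      src <- pmin(pmax(seq_len(n) + o, 1L), n) # replicate edges
      out <- out + w * m[src, , drop = FALSE]
      wsum <- wsum + w
    }
    out
  }
  t(blur1(t(blur1(mat))))
}

# Standardized spatially correlated Gaussian texture: blur an iid N(0, 1)
# field and restore unit marginal variance, so class means and sds applied
# on top are exact regardless of the correlation length.
correlated_noise <- function(h, w, sigma_px) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma_px > 0) {
    z <- gauss_blur(z, sigma_px)
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- (z - mean(z)) / s
  }
  z
}

#' Sample refractive-index and thickness fields
#'
#' Draws the per-pixel tissue refractive index as a Gaussian field with
#' the class mean and sd (truncated to `ri_limits`) and the per-pixel
#' thickness as a Uniform(`thickness_um`) field. Both fields are built
#' from spatially correlated standard-normal textures (correlation length
#' `smooth_sigma_px`) pushed through the exact marginal transforms, so
#' smoothing changes the spatial grain but never the per-pixel
#' distributions. Background pixels get RI 1 (air) and thickness 0.
#' Fully deterministic under a fixed seed.
#'
#' @param spec a [section_spec()].
#' @param seed integer seed.
#' @return List with matrices `ri` and `thickness_nm` (height x width)
#'   and the class `region_map`.
#' @export
sample_fields <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(seed, {
    h <- spec$height; w <- spec$width
    z_ri <- correlated_noise(h, w, spec$smooth_sigma_px)
    z_th <- correlated_noise(h, w, spec$smooth_sigma_px)
    ri <- matrix(1, h, w); th <- matrix(0, h, w)
    for (cls in 1:2) {
      idx <- spec$region_map == cls
      if (!any(idx)) next
      pars <- if (cls == 1) spec$ri_healthy else spec$ri_cancer
      ri[idx] <- pmin(pmax(pars[1] + pars[2] * z_ri[idx],
                           spec$ri_limits[1]), spec$ri_limits[2])
      th[idx] <- if (spec$thickness_dist == "uniform")
        stats::qunif(stats::pnorm(z_th[idx]),
                     spec$thickness_um[1] * 1000,
                     spec$thickness_um[2] * 1000)
      else pmax((spec$thickness_um[1] + spec$thickness_um[2] * z_th[idx]),
                0.05) * 1000
    }
    list(ri = ri, thickness_nm = th, region_map = spec$region_map)
  })
}

#' Color lookup table over (refractive index, thickness)
#'
#' Precomputes the forward-model color (linear sRGB before gamma) on a
#' regular grid of tissue refractive index and thickness, so whole images
#' can be rendered by bilinear interpolation instead of one transfer-matrix
#' evaluation per pixel. The maximum interpolation error (delta-E against
#' exact rendering at random probe points) is recorded in the table.
#'
#' @param spec a [section_spec()] (mode and slide configuration are taken
#'   from it).
#' @param n_nodes,d_nodes grid nodes along RI and thickness (default 64
#'   each).
#' @param n_range,d_range_nm grid extent; defaults cover the spec's RI
#'   truncation limits and thickness distribution (mean +/- 4 sd in the
#'   normal mode).
#' @param n_probe random probe points for the error estimate (default 16).
#' @param seed seed for the probe points.
#' @return Object of class `color_lut`.
#' @export
build_color_lut <- function(spec, n_nodes = 64, d_nodes = 64,
                            n_range = spec$ri_limits,
                            d_range_nm = thickness_range_nm(spec),
                            n_probe = 16, seed = 1) {
  stopifnot(inherits(spec, "section_spec"))
  n_axis <- seq(n_range[1], n_range[2], length.out = n_nodes)
  d_axis <- seq(d_range_nm[1], d_range_nm[2], length.out = d_nodes)
  fwd <- forward_color_fun(spec)
  lin <- array(0, dim = c(n_nodes, d_nodes, 3))
  for (i in seq_len(n_nodes)) for (j in seq_len(d_nodes)) {
    lin[i, j, ] <- fwd(n_axis[i], d_axis[j])
  }
  lut <- structure(list(n_axis = n_axis, d_axis = d_axis, linear_rgb = lin,
                        mode = spec$mode, cavity_nm = spec$slide$cavity_nm),
                   class = "color_lut")
  lut$max_delta_e <- with_seed(seed, {
    pn <- stats::runif(n_probe, n_range[1], n_range[2])
    pd <- stats::runif(n_probe, d_range_nm[1], d_range_nm[2])
    max(vapply(seq_len(n_probe), function(k) {
      exact <- srgb_matrix_to_lab(matrix(srgb_encode(pmin(pmax(
        fwd(pn[k], pd[k]), 0), 1)), 1))
      interp <- srgb_matrix_to_lab(matrix(srgb_encode(pmin(pmax(
        lut_lookup(lut, pn[k], pd[k]), 0), 1)), 1))
      sqrt(sum((exact - interp)^2))
    }, numeric(1)))
  })
  lut
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf(
    "<color_lut> %s mode, %d x %d nodes, RI [%.3g, %.3g], d [%g, %g] nm, max dE %.3g\n",
    x$mode, length(x$n_axis), length(x$d_axis),
    min(x$n_axis), max(x$n_axis), min(x$d_axis), max(x$d_axis),
    x$max_delta_e))
  invisible(x)
}

# Forward model (n, d_nm) -> linear sRGB for the spec's mode; the D65
# rescaling in spectrum_to_color keeps the chain white neutral.
forward_color_fun <- function(spec) {
  if (spec$mode == "nos") {
    function(n, d) {
      col <- simulate_slide_color(n, d, spec$slide)
      srgb_decode(as.numeric(col$srgb))
    }
  } else {
    function(n, d) {
      col <- simulate_glass_color(n, d, spec$slide)
      srgb_decode(as.numeric(col$srgb))
    }
  }
}

# Bilinear LUT interpolation; n, d may be vectors. Returns N x 3 linear
# sRGB. Inputs are clamped to the LUT extent.
lut_lookup <- function(lut, n, d) {
  nx <- lut$n_axis; dx <- lut$d_axis
  n <- pmin(pmax(n, nx[1]), nx[length(nx)])
  d <- pmin(pmax(d, dx[1]), dx[length(dx)])
  fi <- (n - nx[1]) / (nx[2] - nx[1]); i0 <- pmin(floor(fi) + 1, length(nx) - 1)
  fj <- (d - dx[1]) / (dx[2] - dx[1]); j0 <- pmin(floor(fj) + 1, length(dx) - 1)
  u <- fi - (i0 - 1); v <- fj - (j0 - 1)
  out <- matrix(0, length(n), 3)
  for (ch in 1:3) {
    g <- lut$linear_rgb[, , ch]
    out[, ch] <-
      g[cbind(i0, j0)] * (1 - u) * (1 - v) +
      g[cbind(i0 + 1, j0)] * u * (1 - v) +
      g[cbind(i0, j0 + 1)] * (1 - u) * v +
      g[cbind(i0 + 1, j0 + 1)] * u * v
  }
  out
}

#' Render a synthetic section to RGB
#'
#' Maps the per-pixel (RI, thickness) fields through the forward color
#' model (via a bilinear lookup table), adds Gaussian sensor noise in sRGB
#' and clips to \[0, 1\]. Background pixels get the bare-slide color.
#'
#' @param spec a [section_spec()].
#' @param fields as from [sample_fields()]; default: sampled with `seed`.
#' @param lut optional prebuilt [build_color_lut()] (reuse across seeds
#'   for speed); must match the spec's mode.
#' @param seed integer seed (noise, and fields when not supplied).
#' @return Object of class `rendered_section`: list with the `rgb` array
#'   (height x width x 3), `fields`, `spec`, `seed` and `lut_delta_e` (the
#'   LUT's recorded maximum interpolation error).
#' @export
render_section <- function(spec, fields = NULL, lut = NULL, seed = 1) {
  stopifnot(inherits(spec, "section_spec"))
  if (is.null(fields)) fields <- sample_fields(spec, seed = seed)
  if (!all(dim(fields$ri) == c(spec$height, spec$width)))
    stop("fields do not match the spec dimensions")
  if (is.null(lut)) lut <- build_color_lut(spec)
  if (lut$mode != spec$mode) stop("LUT mode does not match spec mode")
  tissue <- fields$region_map > 0
  lin <- matrix(0, spec$height * spec$width, 3)
  if (any(tissue))
    lin[tissue, ] <- lut_lookup(lut, fields$ri[tissue],
                                fields$thickness_nm[tissue])
  if (any(!tissue)) {
    bare <- forward_color_fun(spec)(1, 0)
    lin[!tissue, ] <- matrix(bare, sum(!tissue), 3, byrow = TRUE)
  }
  srgb <- srgb_encode(pmin(pmax(lin, 0), 1))
  rgb <- with_seed(seed + 1L, {
    if (spec$noise_sd > 0)
      srgb <- srgb + stats::rnorm(length(srgb), sd = spec$noise_sd)
    array(pmin(pmax(srgb, 0), 1), dim = c(spec$height, spec$width, 3))
  })
  structure(list(rgb = rgb, fields = fields, spec = spec, seed = seed,
                 lut_delta_e = lut$max_delta_e),
            class = "rendered_section")
}

#' @export
print.rendered_section <- function(x, ...) {
  cat(sprintf("<rendered_section> %d x %d px, %s mode, seed %d, LUT dE %.3g\n",
              x$spec$height, x$spec$width, x$spec$mode, x$seed, x$lut_delta_e))
  invisible(x)
}

#' Write a rendered section to image files
#'
#' Writes the RGB image as PNG or TIFF, plus the truth fields as a CSV
#' manifest (class, RI, thickness per pixel).
#'
#' @param section a `rendered_section`.
#' @param path output image path (`.png` or `.tiff`).
#' @param fields_csv optional CSV path for the per-pixel truth fields.
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path, fields_csv = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(section$rgb, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(section$rgb, path)
  else stop("unsupported output format: ", ext)
  if (!is.null(fields_csv)) {
    f <- section$fields
    utils::write.csv(data.frame(
      row = rep(seq_len(nrow(f$ri)), ncol(f$ri)),
      col = rep(seq_len(ncol(f$ri)), each = nrow(f$ri)),
      class = as.vector(f$region_map),
      ri = as.vector(f$ri),
      thickness_nm = as.vector(f$thickness_nm)), fields_csv,
      row.names = FALSE)
  }
  invisible(path)
}

#' Sample non-overlapping class-pure regions
#'
#' Samples square regions that lie entirely inside one class of the region
#' map and do not overlap each other, either uniformly at random
#' (rejection sampling) or from a grid-aligned tiling (which reaches the
#' map's full packing capacity).
#'
#' @param region_map integer class matrix (0/1/2).
#' @param class_id class to sample from (1 or 2).
#' @param n_regions number of regions.
#' @param size region edge (pixels).
#' @param seed integer seed.
#' @param grid_aligned sample from the non-overlapping `size`-aligned
#'   tiling instead of uniform placement.
#' @param max_tries rejection-sampling budget (uniform placement only).
#' @return List of `c(row, col)` top-left corners.
#' @export
sample_regions <- function(region_map, class_id, n_regions, size,
                           seed = 1, grid_aligned = FALSE, max_tries = 2000) {
  ok_corner <- function(r, c)
    all(region_map[r:(r + size - 1), c:(c + size - 1)] == class_id)
  with_seed(seed, {
    if (grid_aligned) {
      cand <- expand.grid(
        r = seq(1, nrow(region_map) - size + 1, by = size),
        c = seq(1, ncol(region_map) - size + 1, by = size))
      pure <- cand[mapply(ok_corner, cand$r, cand$c), , drop = FALSE]
      if (nrow(pure) < n_regions)
        stop(sprintf("capacity: only %d class-pure %dpx tiles available, %d requested",
                     nrow(pure), size, n_regions))
      pick <- pure[sample.int(nrow(pure), n_regions), , drop = FALSE]
      return(lapply(seq_len(nrow(pick)),
                    function(i) c(pick$r[i], pick$c[i])))
    }
    chosen <- list()
    tries <- 0
    while (length(chosen) < n_regions && tries < max_tries) {
      tries <- tries + 1
      r <- sample.int(nrow(region_map) - size + 1, 1)
      c <- sample.int(ncol(region_map) - size + 1, 1)
      overlap <- any(vapply(chosen, function(p)
        abs(p[1] - r) < size && abs(p[2] - c) < size, logical(1)))
      if (!overlap && ok_corner(r, c)) chosen[[length(chosen) + 1]] <- c(r, c)
    }
    if (length(chosen) < n_regions)
      stop(sprintf("could only place %d of %d non-overlapping %dpx regions",
                   length(chosen), n_regions, size))
    chosen
  })
}

#' Generate labeled class-pure tiles with a subject-level split
#'
#' Renders one synthetic section per "subject" (each with its own derived
#' seed) and cuts non-overlapping class-pure tiles from it. Train and test
#' tiles come from disjoint subject seed sets, emulating a patient-level
#' split.
#'
#' @param spec a [section_spec()].
#' @param n_per_class tiles per class per split.
#' @param tile_px tile edge length (pixels).
#' @param n_subjects subjects per split (tiles are spread evenly).
#' @param seed integer seed; subject seeds are derived from it.
#' @param lut optional prebuilt [build_color_lut()].
#' @return List with `train` and `test`, each a list with `tiles` (list of
#'   tile RGB arrays), `labels` (factor healthy/cancerous) and `subjects`
#'   (integer subject ids); subject id sets are disjoint between splits.
#' @export
make_labeled_tiles <- function(spec, n_per_class = 10, tile_px = 24,
                               n_subjects = 2, seed = 1, lut = NULL) {
  stopifnot(inherits(spec, "section_spec"))
  if (n_per_class == 0)
    return(list(train = list(tiles = list(), labels = factor(character(0),
                  levels = c("healthy", "cancerous")), subjects = integer(0)),
                test = list(tiles = list(), labels = factor(character(0),
                  levels = c("healthy", "cancerous")), subjects = integer(0))))
  if (is.null(lut)) lut <- build_color_lut(spec)
  split_ids <- list(train = seq_len(n_subjects),
                    test = n_subjects + seq_len(n_subjects))
  per_subject <- ceiling(n_per_class / n_subjects)
  out <- lapply(split_ids, function(ids) {
    tiles <- list(); labels <- character(0); subjects <- integer(0)
    for (sid in ids) {
      sec <- render_section(spec, lut = lut, seed = seed * 1000L + sid)
      for (cls in 1:2) {
        want <- min(per_subject, n_per_class - sum(labels ==
                      c("healthy", "cancerous")[cls]))
        if (want <= 0) next
        corners <- sample_regions(spec$region_map, cls, want, tile_px,
                                  seed = seed * 1000L + sid + 500L * cls,
                                  grid_aligned = TRUE)
        for (p in corners) {
          tiles[[length(tiles) + 1]] <-
            sec$rgb[p[1]:(p[1] + tile_px - 1), p[2]:(p[2] + tile_px - 1), ,
                    drop = FALSE]
          labels <- c(labels, c("healthy", "cancerous")[cls])
          subjects <- c(subjects, sid)
        }
      }
    }
    list(tiles = tiles,
         labels = factor(labels, levels = c("healthy", "cancerous")),
         subjects = subjects)
  })
  names(out) <- c("train", "test")
  out
}

#' Simulate two conditionally independent raters
#'
#' Given a truth class per item and a row-stochastic confusion model
#' (probability of each called class given the truth), draws two raters'
#' calls independently given the truth.
#'
#' @param truth factor (or character) truth class per item.
#' @param confusion_model K x K matrix, rows = truth class, columns =
#'   called class, each row summing to 1; rows/columns ordered like
#'   `levels(truth)`. A scalar `error` is also accepted: diagonal
#'   1 - error, off-diagonal error/(K-1).
#' @param seed integer seed.
#' @return List with factors `rater1` and `rater2`.
#' @export
simulate_raters <- function(truth, confusion_model = 0, seed = 1) {
  truth <- as.factor(truth)
  K <- nlevels(truth)
  if (is.numeric(confusion_model) && length(confusion_model) == 1) {
    e <- confusion_model
    confusion_model <- matrix(e / (K - 1), K, K)
    diag(confusion_model) <- 1 - e
  }
  if (!is.matrix(confusion_model) || any(dim(confusion_model) != K))
    stop("confusion_model must be K x K for K truth classes")
  if (any(confusion_model < 0) ||
      any(abs(rowSums(confusion_model) - 1) > 1e-8))
    stop("confusion_model rows must be probabilities summing to 1")
  with_seed(seed, {
    draw <- function() {
      idx <- vapply(as.integer(truth), function(t)
        sample.int(K, 1, prob = confusion_model[t, ]), integer(1))
      factor(levels(truth)[idx], levels = levels(truth))
    }
    list(rater1 = draw(), rater2 = draw())
  })
}

# Per-tile color features: mean and sd of L*, a*, b*.
tile_features <- function(tiles) {
  t(vapply(tiles, function(tile) {
    rgbm <- cbind(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
                  as.vector(tile[, , 3]))
    lab <- srgb_matrix_to_lab(rgbm)
    c(colMeans(lab), apply(lab, 2, stats::sd))
  }, numeric(6)))
}

#' Baseline color-feature tile classifier
#'
#' A deliberately shallow stand-in for a deep tile classifier: per-tile
#' features are the mean and standard deviation of L*, a*, b*, and the
#' score is either a nearest-centroid contrast (default) or a logistic
#' regression probability. Scores are continuous in \[0, 1\] with higher
#' values meaning "cancerous", suitable for ROC/AUC evaluation.
#'
#' @param train_tiles,train_labels training tiles (list of RGB arrays) and
#'   their factor labels (level 2 = positive class).
#' @param test_tiles tiles to score.
#' @param method `"centroid"` or `"logistic"`.
#' @return Numeric score per test tile.
#' @export
baseline_tile_classifier <- function(train_tiles, train_labels, test_tiles,
                                     method = c("centroid", "logistic")) {
  method <- match.arg(method)
  train_labels <- as.factor(train_labels)
  if (nlevels(droplevels(train_labels)) < 2)
    stop("training set must contain both classes")
  Xtr <- tile_features(train_tiles)
  Xte <- tile_features(test_tiles)
  pos <- levels(train_labels)[2]
  if (method == "centroid") {
    mu_pos <- colMeans(Xtr[train_labels == pos, , drop = FALSE])
    mu_neg <- colMeans(Xtr[train_labels != pos, , drop = FALSE])
    d_pos <- sqrt(rowSums(sweep(Xte, 2, mu_pos)^2))
    d_neg <- sqrt(rowSums(sweep(Xte, 2, mu_neg)^2))
    0.5 * (1 + (d_neg - d_pos) / pmax(d_neg + d_pos, .Machine$double.eps))
  } else {
    df <- data.frame(y = as.integer(train_labels == pos), Xtr)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    as.numeric(stats::predict(fit, newdata = data.frame(Xte),
                              type = "response"))
  }
}
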
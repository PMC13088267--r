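#' NOS slide configuration
#'
#' Bundles the optical configuration of a nanocavity-on-silicon slide: the
#' Si3N4 cavity thickness, material tables, wavelength grid, illumination
#' geometry and illuminant. The default 243 nm cavity is the green slide of
#' the six-color series (85, 111, 158, 197, 243, 268 nm rendering blue,
#' gray, yellow, purple, green, pink).
#'
#' @param cavity_nm Si3N4 cavity thickness in nm (fabrication range is
#'   roughly 40-320 nm).
#' @param angle angle of incidence, degrees from normal.
#' @param polarization `"unpolarized"`, `"s"` or `"p"`.
#' @param illuminant illuminant name for the color chain (see
#'   [illuminant_spectrum()]).
#' @param wavelengths wavelength grid (nm).
#' @param cavity_material,substrate_material,ambient dispersion tables;
#'   defaults are the bundled Si3N4 and Si and air.
#' @return Object of class `slide_config`.
#' @export
slide_config <- function(cavity_nm = 243, angle = 0,
                         polarization = "unpolarized", illuminant = "E",
                         wavelengths = default_wavelengths(),
                         cavity_material = nos_material("si3n4"),
                         substrate_material = nos_material("si"),
                         ambient = nos_material("air")) {
  if (!is.finite(cavity_nm) || cavity_nm <= 0)
    stop("cavity_nm must be a positive number")
  structure(list(cavity_nm = cavity_nm, angle = angle,
                 polarization = polarization, illuminant = illuminant,
                 wavelengths = as.numeric(wavelengths),
                 cavity_material = cavity_material,
                 substrate_material = substrate_material,
                 ambient = ambient),
            class = "slide_config")
}

#' @export
print.slide_config <- function(x, ...) {
  cat(sprintf(
    "<slide_config> cavity %g nm %s on %s, angle %g deg, %s, illuminant %s\n",
    x$cavity_nm, x$cavity_material$material_id,
    x$substrate_material$material_id, x$angle, x$polarization, x$illuminant))
  invisible(x)
}

# Stack for a tissue layer of index n and thickness d on the slide.
slide_stack <- function(config, tissue_n, tissue_thickness_nm) {
  layers <- list()
  if (tissue_thickness_nm > 0)
    layers <- list(list(dispersion = constant_dispersion(tissue_n, 0, "tissue"),
                        thickness_nm = tissue_thickness_nm))
  layers <- c(layers, list(list(dispersion = config$cavity_material,
                                thickness_nm = config$cavity_nm)))
  layer_stack(layers = layers, substrate = config$substrate_material,
              ambient = config$ambient)
}

# Color chain shared by the slide and glass forward models: spectrum ->
# XYZ -> Lab (chain white) -> sRGB (XYZ rescaled to the D65 axes so the
# chain white encodes as neutral).
spectrum_to_color <- function(spec, config) {
  xyz <- spectrum_to_tristimulus(spec, illuminant = config$illuminant)
  white <- chain_white(config$illuminant, spec$wavelength_nm)
  lab <- xyz_to_lab(xyz, white = white)
  d65 <- d65_white()
  adapted <- tristimulus(xyz$X * d65$X / white$X,
                         xyz$Y * d65$Y / white$Y,
                         xyz$Z * d65$Z / white$Z)
  srgb <- xyz_to_srgb(adapted)
  structure(list(spectrum = spec, xyz = xyz, lab = lab, srgb = srgb,
                 clipped = attr(srgb, "clipped")),
            class = "nos_color")
}

#' @export
print.nos_color <- function(x, ...) {
  cat(sprintf(
    "<nos_color> (x,y)=(%.4f, %.4f)  L*a*b*=(%.2f, %.2f, %.2f)  sRGB=(%.3f, %.3f, %.3f)%s\n",
    x$xyz$x, x$xyz$y, x$lab[["L"]], x$lab[["a"]], x$lab[["b"]],
    x$srgb[["r"]], x$srgb[["g"]], x$srgb[["b"]],
    if (isTRUE(x$clipped)) " [gamut-clipped]" else ""))
  invisible(x)
}

#' Simulate the structural color of tissue on a NOS slide
#'
#' Composes the air / tissue / Si3N4 / Si stack, computes its
#' transfer-matrix reflectance on the configured wavelength grid, and
#' converts it through the CIE chain to chromaticity, CIELAB and sRGB.
#' Deterministic: the same inputs always give the same color.
#'
#' @param tissue_n real refractive index of the (non-dispersive) tissue
#'   layer; healthy colorectal epithelium clusters near 1.27, cancerous
#'   near 1.37.
#' @param tissue_thickness_nm tissue layer thickness in nm; 0 gives the
#'   bare slide color. Dewaxed nominal-2-um sections measure 300-1000 nm.
#' @param config a [slide_config()].
#' @return Object of class `nos_color`: list with `spectrum`
#'   ([nos_spectrum()]), `xyz` (`tristimulus`), `lab` (`lab_point`), `srgb`
#'   and a gamut-`clipped` flag.
#' @examples
#' simulate_slide_color(1.37, 500)
#' @export
simulate_slide_color <- function(tissue_n = 1.37, tissue_thickness_nm = 500,
                                 config = slide_config()) {
  if (!is.finite(tissue_thickness_nm) || tissue_thickness_nm < 0)
    stop("tissue_thickness_nm must be >= 0")
  if (!is.finite(tissue_n) || tissue_n <= 0) stop("tissue_n must be > 0")
  spec <- tmm_reflectance(slide_stack(config, tissue_n, tissue_thickness_nm),
                          wavelengths = config$wavelengths,
                          angle = config$angle,
                          polarization = config$polarization)
  spectrum_to_color(spec, config)
}

#' Weak-contrast glass-slide color proxy
#'
#' A deliberately simple stand-in for an unstained section on a plain glass
#' slide, where no interference cavity exists and contrast comes only from
#' the small Fresnel losses at the tissue interfaces: the wavelength-flat
#' transmittance T = (1 - ((n-1)/(n+1))^2)^2 is pushed through the same
#' color chain. Synthetic-only: this is a contrast model for simulation
#' experiments, not an optical model of a real glass slide.
#'
#' @inheritParams simulate_slide_color
#' @return A `nos_color`.
#' @export
simulate_glass_color <- function(tissue_n = 1.37, tissue_thickness_nm = 500,
                                 config = slide_config()) {
  if (!is.finite(tissue_n) || tissue_n <= 0) stop("tissue_n must be > 0")
  rfres <- ((tissue_n - 1) / (tissue_n + 1))^2
  tval <- if (tissue_thickness_nm > 0) (1 - rfres)^2 else 1
  spec <- nos_spectrum(config$wavelengths,
                       rep(tval, length(config$wavelengths)))
  spectrum_to_color(spec, config)
}

#' Sweep tissue refractive index or thickness
#'
#' Renders the slide color along a sweep of one tissue parameter and
#' returns the chromaticity/CIELAB trajectory, e.g. the n = 1.22-1.47
#' trajectory on the green slide.
#'
#' @param values numeric values of the swept parameter.
#' @param param `"tissue_n"` or `"tissue_thickness"`.
#' @param tissue_n,tissue_thickness_nm fixed value of the other parameter.
#' @param config a [slide_config()].
#' @return Data frame with the swept value, chromaticity `x`, `y`, and
#'   `L`, `a`, `b`.
#' @export
sweep_slide_color <- function(values, param = c("tissue_n", "tissue_thickness"),
                              tissue_n = 1.37, tissue_thickness_nm = 500,
                              config = slide_config()) {
  param <- match.arg(param)
  rows <- lapply(values, function(v) {
    col <- if (param == "tissue_n")
      simulate_slide_color(v, tissue_thickness_nm, config)
    else simulate_slide_color(tissue_n, v, config)
    data.frame(value = v, x = col$xyz$x, y = col$xyz$y,
               L = col$lab[["L"]], a = col$lab[["a"]], b = col$lab[["b"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  out
}

#' Just-noticeable-difference sensitivity scan
#'
#' Finds the smallest fractional perturbation of one tissue parameter
#' (refractive index or thickness) that moves the slide color by at least a
#' given CIELAB delta-E threshold. Both perturbation directions are
#' scanned; for each, a coarse grid locates the first threshold crossing
#' and bisection refines it to the requested relative tolerance.
#'
#' @param param `"tissue_n"` or `"tissue_thickness"`.
#' @param tissue_n,tissue_thickness_nm baseline tissue parameters.
#' @param jnd_threshold delta-E*ab threshold; default 2.3, the classical
#'   just-noticeable difference.
#' @param config a [slide_config()].
#' @param max_frac largest fractional perturbation searched (default 0.5).
#' @param tol relative bisection tolerance on the returned fraction.
#' @return List of class `jnd_scan` with `plus` and `minus` (fractional
#'   perturbation per direction, NA if the threshold is not reached within
#'   `max_frac`), `fraction` (their minimum) and `percent` (100 x fraction).
#' @export
jnd_fraction_scan <- function(param = c("tissue_n", "tissue_thickness"),
                              tissue_n = 1.37, tissue_thickness_nm = 500,
                              jnd_threshold = 2.3, config = slide_config(),
                              max_frac = 0.5, tol = 1e-3) {
  param <- match.arg(param)
  if (!is.finite(jnd_threshold) || jnd_threshold < 0)
    stop("jnd_threshold must be >= 0")
  base <- simulate_slide_color(tissue_n, tissue_thickness_nm, config)
  de_at <- function(frac) {
    col <- if (param == "tissue_n")
      simulate_slide_color(tissue_n * (1 + frac), tissue_thickness_nm, config)
    else simulate_slide_color(tissue_n, tissue_thickness_nm * (1 + frac), config)
    delta_e(base$lab, col$lab)
  }
  find_dir <- function(sign) {
    if (jnd_threshold == 0) return(0)
    grid <- sign * seq(0, max_frac, length.out = 65)[-1]
    de <- vapply(grid, de_at, numeric(1))
    hit <- which(de >= jnd_threshold)
    if (length(hit) == 0) return(NA_real_)
    hi <- grid[hit[1]]
    lo <- if (hit[1] == 1) 0 else grid[hit[1] - 1]
    while (abs(hi - lo) > tol * abs(hi)) {
      mid <- (lo + hi) / 2
      if (de_at(mid) >= jnd_threshold) hi <- mid else lo <- mid
    }
    abs(hi)
  }
  plus <- find_dir(1); minus <- find_dir(-1)
  frac <- suppressWarnings(min(plus, minus, na.rm = TRUE))
  if (!is.finite(frac))
    stop(sprintf("delta-E threshold %g not reached within +/-%g%% perturbation",
                 jnd_threshold, 100 * max_frac))
  structure(list(param = param, threshold = jnd_threshold,
                 plus = plus, minus = minus,
                 fraction = frac, percent = 100 * frac),
            class = "jnd_scan")
}

#' @export
print.jnd_scan <- function(x, ...) {
  cat(sprintf(
    "<jnd_scan> %s: %.3f%% fractional change reaches delta-E %.2f (+%s / -%s)\n",
    x$param, x$percent, x$threshold,
    ifelse(is.na(x$plus), "not reached", sprintf("%.3f%%", 100 * x$plus)),
    ifelse(is.na(x$minus), "not reached", sprintf("%.3f%%", 100 * x$minus))))
  invisible(x)
}
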
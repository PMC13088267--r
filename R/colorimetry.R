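# CIE colorimetry: spectrum -> XYZ -> (x, y), CIELAB, delta-E, sRGB.
# The bundled observer is an analytic piecewise-Gaussian approximation of
# the CIE 1931 2-degree color-matching functions (synthetic table, see
# extdata); channels are scaled to a common integral so the equal-energy
# white sits exactly at chromaticity (1/3, 1/3).

.noscolor_env <- new.env(parent = emptyenv())

#' Color-matching functions of the bundled standard observer
#'
#' Returns the package's 2-degree observer color-matching functions,
#' resampled (linear interpolation, zero outside the tabulated span) onto
#' the requested wavelength grid.
#'
#' @param wavelengths wavelength grid (nm); default [default_wavelengths()].
#' @return Data frame with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @export
cmf_table <- function(wavelengths = default_wavelengths()) {
  if (is.null(.noscolor_env$cmf)) {
    path <- system.file("extdata", "cie1931_cmf_2deg_synthetic.csv",
                        package = "noscolor", mustWork = TRUE)
    .noscolor_env$cmf <- utils::read.csv(path)
  }
  raw <- .noscolor_env$cmf
  res <- function(v) stats::approx(raw$wavelength_nm, v, xout = wavelengths,
                                   yleft = 0, yright = 0)$y
  data.frame(wavelength_nm = as.numeric(wavelengths),
             xbar = res(raw$xbar), ybar = res(raw$ybar), zbar = res(raw$zbar))
}

#' Illuminant spectral power distribution
#'
#' `"E"` is the equal-energy illuminant (constant spectrum), the implicit
#' illuminant of a color chain that integrates reflectance directly against
#' the color-matching functions. `"planck6500"` is a smooth daylight-like
#' alternative: a 6500 K Planckian radiator normalized to 100 at 560 nm
#' (an approximation, not the CIE D65 table).
#'
#' @param name `"E"` or `"planck6500"`.
#' @param wavelengths wavelength grid (nm).
#' @return Numeric vector of relative spectral power, one per wavelength.
#' @export
illuminant_spectrum <- function(name = c("E", "planck6500"),
                                wavelengths = default_wavelengths()) {
  name <- match.arg(name)
  wavelengths <- as.numeric(wavelengths)
  if (name == "E") return(rep(100, length(wavelengths)))
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23; Tt <- 6500
  planck <- function(l_nm) {
    l <- l_nm * 1e-9
    1 / (l^5 * (exp(h * c0 / (l * kB * Tt)) - 1))
  }
  100 * planck(wavelengths) / planck(560)
}

#' Tristimulus values from a reflectance spectrum
#'
#' Integrates R(lambda) * S(lambda) against the observer color-matching
#' functions by rectangular summation on the spectrum's grid and normalizes
#' so a perfect reflector (R = 1) has Y = 100. Chromaticity (x, y) is the
#' normalized projection X/(X+Y+Z), Y/(X+Y+Z).
#'
#' @param r a [nos_spectrum()] (or data frame with `wavelength_nm` and
#'   `reflectance`).
#' @param illuminant illuminant name (see [illuminant_spectrum()]) or a
#'   numeric vector of spectral power on the same grid as `r`.
#' @param cmf optional data frame as returned by [cmf_table()] on the same
#'   grid; defaults to the bundled observer resampled to `r`'s grid.
#' @return Object of class `tristimulus`: list with `X`, `Y`, `Z`, `x`, `y`.
#' @export
spectrum_to_tristimulus <- function(r, illuminant = "E", cmf = NULL) {
  if (!all(c("wavelength_nm", "reflectance") %in% names(r)))
    stop("r must have wavelength_nm and reflectance columns")
  wl <- r$wavelength_nm
  if (is.character(illuminant)) {
    S <- illuminant_spectrum(illuminant, wl)
  } else {
    S <- as.numeric(illuminant)
    if (length(S) != length(wl))
      stop("illuminant grid does not match spectrum grid")
  }
  if (is.null(cmf)) cmf <- cmf_table(wl)
  if (nrow(cmf) != length(wl) || any(abs(cmf$wavelength_nm - wl) > 1e-9))
    stop("cmf grid does not match spectrum grid")
  Kn <- 100 / sum(S * cmf$ybar)
  tristimulus(
    X = Kn * sum(r$reflectance * S * cmf$xbar),
    Y = Kn * sum(r$reflectance * S * cmf$ybar),
    Z = Kn * sum(r$reflectance * S * cmf$zbar)
  )
}

#' Tristimulus constructor
#'
#' @param X,Y,Z non-negative tristimulus values (perfect-reflector Y = 100
#'   convention).
#' @return Object of class `tristimulus` with chromaticity `x`, `y` filled
#'   in when X + Y + Z > 0.
#' @export
tristimulus <- function(X, Y, Z) {
  stopifnot(is.finite(X), is.finite(Y), is.finite(Z))
  if (min(X, Y, Z) < -1e-9) stop("tristimulus values must be non-negative")
  s <- X + Y + Z
  structure(list(X = X, Y = Y, Z = Z,
                 x = if (s > 0) X / s else NA_real_,
                 y = if (s > 0) Y / s else NA_real_),
            class = "tristimulus")
}

#' @export
print.tristimulus <- function(x, ...) {
  cat(sprintf("<tristimulus> X=%.4f Y=%.4f Z=%.4f (x=%.4f, y=%.4f)\n",
              x$X, x$Y, x$Z, x$x, x$y))
  invisible(x)
}

#' Chromaticity coordinates from tristimulus values
#'
#' @param t a `tristimulus` (or list with X, Y, Z).
#' @return Named numeric `c(x, y)`.
#' @export
tristimulus_to_xy <- function(t) {
  s <- t$X + t$Y + t$Z
  if (!is.finite(s) || s <= 0)
    stop("chromaticity undefined: X + Y + Z must be > 0")
  c(x = t$X / s, y = t$Y / s)
}

#' White point of the spectral color chain
#'
#' Tristimulus of a perfect reflector under the given illuminant and
#' observer: the reference white used for CIELAB conversion of simulated
#' spectra.
#'
#' @inheritParams spectrum_to_tristimulus
#' @param wavelengths wavelength grid (nm).
#' @return A `tristimulus` with Y = 100.
#' @export
chain_white <- function(illuminant = "E", wavelengths = default_wavelengths()) {
  spectrum_to_tristimulus(nos_spectrum(wavelengths, rep(1, length(wavelengths))),
                          illuminant = illuminant)
}

# D65 white (Y = 100 scale), used for image-side sRGB <-> Lab conversions.
d65_white <- function() tristimulus(95.047, 100, 108.883)

#' CIELAB coordinates from tristimulus values
#'
#' Standard CIE 1976 L*a*b* transform with the cube-root / linear-segment
#' companding, relative to the given reference white.
#'
#' @param t a `tristimulus`.
#' @param white reference white `tristimulus` with strictly positive
#'   components (default: equal-energy chain white).
#' @return Object of class `lab_point`: named numeric `c(L, a, b)`.
#' @export
xyz_to_lab <- function(t, white = chain_white()) {
  if (min(white$X, white$Y, white$Z) <= 0)
    stop("reference white must have strictly positive components")
  f <- function(x) {
    d <- 6 / 29
    ifelse(x > d^3, x^(1/3), x / (3 * d^2) + 4 / 29)
  }
  fx <- f(t$X / white$X); fy <- f(t$Y / white$Y); fz <- f(t$Z / white$Z)
  structure(c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz)),
            class = "lab_point")
}

#' @export
print.lab_point <- function(x, ...) {
  cat(sprintf("<lab_point> L*=%.3f a*=%.3f b*=%.3f\n", x[["L"]], x[["a"]], x[["b"]]))
  invisible(x)
}

#' CIE76 color difference
#'
#' Euclidean distance between two CIELAB points (delta-E*ab). A delta-E near
#' 2.3 is the classical just-noticeable difference.
#'
#' @param p,q CIELAB points: named numerics with components L, a, b.
#' @return Non-negative scalar.
#' @export
delta_e <- function(p, q) {
  p <- unclass(p)[c("L", "a", "b")]; q <- unclass(q)[c("L", "a", "b")]
  sqrt(sum((p - q)^2))
}

# sRGB <-> linear and matrices (IEC 61966-2-1, D65 white).
srgb_encode <- function(u) ifelse(u <= 0.0031308, 12.92 * u,
                                  1.055 * u^(1 / 2.4) - 0.055)
srgb_decode <- function(v) ifelse(v <= 0.04045, v / 12.92,
                                  ((v + 0.055) / 1.055)^2.4)
xyz_to_rgb_matrix <- function() matrix(c(
  3.2404542, -1.5371385, -0.4985314,
  -0.9692660, 1.8760108, 0.0415560,
  0.0556434, -0.2040259, 1.0572252), nrow = 3, byrow = TRUE)
rgb_to_xyz_matrix <- function() matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

#' Tristimulus to sRGB
#'
#' Standard sRGB transform (D65-relative XYZ, Y = 100 scale): linear matrix,
#' then gamma encoding. Out-of-gamut channels are clipped to \[0, 1\] and
#' the clipping is flagged in the `"clipped"` attribute.
#'
#' @param t a `tristimulus`.
#' @return Named numeric `c(r, g, b)` in \[0, 1\], attribute `clipped`
#'   logical.
#' @export
xyz_to_srgb <- function(t) {
  lin <- as.vector(xyz_to_rgb_matrix() %*% c(t$X, t$Y, t$Z) / 100)
  clipped <- any(lin < -1e-9 | lin > 1 + 1e-9)
  lin <- pmin(pmax(lin, 0), 1)
  out <- srgb_encode(lin)
  names(out) <- c("r", "g", "b")
  attr(out, "clipped") <- clipped
  out
}

#' sRGB to tristimulus
#'
#' Inverse of [xyz_to_srgb()] for in-gamut colors.
#'
#' @param rgb numeric length-3 sRGB triplet in \[0, 1\].
#' @return A `tristimulus` (Y = 100 scale, D65-relative).
#' @export
srgb_to_xyz <- function(rgb) {
  stopifnot(length(rgb) == 3, all(rgb >= 0), all(rgb <= 1))
  xyz <- as.vector(rgb_to_xyz_matrix() %*% srgb_decode(as.numeric(rgb))) * 100
  tristimulus(xyz[1], xyz[2], xyz[3])
}

# Vectorized sRGB (N x 3, [0,1]) -> Lab (N x 3) under D65/2deg; the
# image-side path used for point-cloud extraction and tile features.
srgb_matrix_to_lab <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  xyz <- srgb_decode(rgb) %*% t(rgb_to_xyz_matrix())
  w <- d65_white(); wv <- c(w$X, w$Y, w$Z) / 100
  d <- 6 / 29
  f <- function(x) ifelse(x > d^3, x^(1/3), x / (3 * d^2) + 4 / 29)
  fx <- f(xyz[, 1] / wv[1]); fy <- f(xyz[, 2] / wv[2]); fz <- f(xyz[, 3] / wv[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}
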
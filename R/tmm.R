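#' Optical layer stack
#'
#' An ordered coherent multilayer: semi-infinite ambient on top, zero or more
#' finite layers, and a semi-infinite substrate. The substrate being
#' semi-infinite means no back-surface reflection is modelled, which is the
#' right treatment for an opaque silicon wafer in the visible.
#'
#' @param layers list of layers, each `list(dispersion = <dispersion_table>,
#'   thickness_nm = <positive number>)`; may be empty (bare interface).
#' @param substrate `dispersion_table` of the semi-infinite substrate.
#' @param ambient `dispersion_table` of the incidence medium (default air).
#' @return An object of class `layer_stack`.
#' @examples
#' layer_stack(
#'   layers = list(list(dispersion = nos_material("si3n4"), thickness_nm = 111)),
#'   substrate = nos_material("si")
#' )
#' @export
layer_stack <- function(layers = list(), substrate,
                        ambient = constant_dispersion(1, 0, "air")) {
  stopifnot(inherits(substrate, "dispersion_table"),
            inherits(ambient, "dispersion_table"))
  if (!is.list(layers)) stop("layers must be a list")
  for (ly in layers) {
    if (!is.list(ly) || !inherits(ly$dispersion, "dispersion_table"))
      stop("each layer needs a $dispersion dispersion_table")
    d <- ly$thickness_nm
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0)
      stop("layer thickness_nm must be a finite non-negative number")
  }
  structure(list(ambient = ambient, layers = layers, substrate = substrate),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %s | %s | %s (semi-infinite)\n",
              x$ambient$material_id,
              if (length(x$layers) == 0) "(no layers)" else
                paste(vapply(x$layers, function(l)
                  sprintf("%s %.4g nm", l$dispersion$material_id, l$thickness_nm),
                  character(1)), collapse = " | "),
              x$substrate$material_id))
  invisible(x)
}

#' Reflectance spectrum container
#'
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param values reflectance per wavelength, each in \[0, 1\] for a passive
#'   stack.
#' @return Object of class `nos_spectrum`: a data frame with columns
#'   `wavelength_nm` and `reflectance`.
#' @export
nos_spectrum <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths); values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths) == 0L) stop("empty spectrum")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(data.frame(wavelength_nm = wavelengths, reflectance = values),
            class = c("nos_spectrum", "data.frame"))
}

#' @export
plot.nos_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$reflectance, type = "l",
                 xlab = "wavelength (nm)", ylab = "reflectance", ylim = c(0, 1), ...)
  invisible(x)
}

#' Default wavelength grid
#'
#' 360-830 nm at 1 nm steps, the grid used throughout the color chain.
#' @return Integer-valued numeric vector.
#' @export
default_wavelengths <- function() seq(360, 830, by = 1)

# Characteristic-matrix reflectance for one polarization.
# n_amb, n_sub: complex vectors over wavelengths; layer_n: list of complex
# vectors; layer_d: thicknesses (nm). xi = n_amb * sin(theta0) is conserved.
tmm_reflectance_pol <- function(wl, n_amb, layer_n, layer_d, n_sub,
                                sin0, pol) {
  xi <- n_amb * sin0
  eta_of <- function(nn) {
    cost <- sqrt(1 - (xi / nn)^2)
    if (pol == "s") nn * cost else nn / cost
  }
  eta0 <- eta_of(n_amb)
  etas <- eta_of(n_sub)
  # running product of characteristic matrices, applied to (1, eta_sub)
  B <- rep(1 + 0i, length(wl)); C <- etas
  if (length(layer_d)) {
    for (j in rev(seq_along(layer_d))) {
      nn <- layer_n[[j]]
      cost <- sqrt(1 - (xi / nn)^2)
      delta <- 2 * pi * nn * cost * layer_d[j] / wl
      eta <- if (pol == "s") nn * cost else nn / cost
      cd <- cos(delta); sd <- sin(delta)
      B2 <- cd * B + (1i * sd / eta) * C
      C2 <- (1i * eta * sd) * B + cd * C
      B <- B2; C <- C2
    }
  }
  r <- (eta0 * B - C) / (eta0 * B + C)
  Mod(r)^2
}

#' Transfer-matrix reflectance of a multilayer
#'
#' Coherent thin-film reflectance of a `layer_stack` by the characteristic
#' (Abeles) matrix method. The complex index convention is n - i k with
#' exp(+i omega t) time dependence; the substrate is semi-infinite. At
#' oblique incidence Snell's law is applied with the principal complex
#' square root; `"unpolarized"` is the mean of the s and p intensities.
#'
#' @param stack a `layer_stack`.
#' @param wavelengths wavelength grid (nm); default [default_wavelengths()].
#' @param angle angle of incidence from the normal, degrees in \[0, 90).
#' @param polarization `"unpolarized"` (default), `"s"` or `"p"`.
#' @return A [nos_spectrum()] with reflectance in \[0, 1\].
#' @examples
#' st <- layer_stack(substrate = constant_dispersion(3))
#' tmm_reflectance(st, 550)$reflectance  # ((1-3)/(1+3))^2 = 0.25
#' @export
tmm_reflectance <- function(stack, wavelengths = default_wavelengths(),
                            angle = 0, polarization = c("unpolarized", "s", "p")) {
  stopifnot(inherits(stack, "layer_stack"))
  polarization <- match.arg(polarization)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) == 0L) stop("empty wavelength grid")
  if (!is.finite(angle) || angle < 0 || angle >= 90)
    stop("angle must be in [0, 90) degrees")
  n_amb <- interpolate_dispersion(stack$ambient, wavelengths)
  n_sub <- interpolate_dispersion(stack$substrate, wavelengths)
  layer_n <- lapply(stack$layers, function(l)
    interpolate_dispersion(l$dispersion, wavelengths))
  layer_d <- vapply(stack$layers, function(l) l$thickness_nm, numeric(1))
  sin0 <- sin(angle * pi / 180)
  pols <- if (polarization == "unpolarized") c("s", "p") else polarization
  R <- rowMeans(matrix(unlist(lapply(pols, function(p)
    tmm_reflectance_pol(wavelengths, n_amb, layer_n, layer_d, n_sub, sin0, p))),
    ncol = length(pols)))
  if (any(R < -1e-9 | R > 1 + 1e-9))
    stop("reflectance outside [0, 1]: non-passive stack or numerical failure")
  nos_spectrum(wavelengths, pmin(pmax(R, 0), 1))
}
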
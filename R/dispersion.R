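#' Material dispersion tables
#'
#' A dispersion table holds the complex optical constants of one material as
#' samples (wavelength in nm, refractive index n, extinction coefficient k).
#' Wavelengths must be strictly increasing, n positive and k non-negative.
#' Queries between samples are linearly interpolated; queries outside the
#' tabulated span are an error (no extrapolation).
#'
#' @param wavelength_nm numeric vector of strictly increasing wavelengths (nm).
#' @param n real refractive index at each wavelength (> 0).
#' @param k extinction coefficient at each wavelength (>= 0); recycled if
#'   length 1.
#' @param material_id short label for the material.
#' @return An object of class `dispersion_table`.
#' @examples
#' glass <- dispersion_table(c(300, 900), c(1.52, 1.51), 0, "glass")
#' interpolate_dispersion(glass, c(400, 600))
#' @export
dispersion_table <- function(wavelength_nm, n, k = 0, material_id = "material") {
  wavelength_nm <- as.numeric(wavelength_nm)
  n <- as.numeric(n)
  k <- rep_len(as.numeric(k), length(wavelength_nm))
  if (length(wavelength_nm) < 1L || length(n) != length(wavelength_nm))
    stop("wavelength_nm and n must have equal positive length")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(n)) || any(!is.finite(k)))
    stop("dispersion samples must be finite")
  if (any(n <= 0)) stop("refractive index n must be > 0")
  if (any(k < 0)) stop("extinction coefficient k must be >= 0")
  structure(
    list(material_id = material_id, wavelength_nm = wavelength_nm, n = n, k = k),
    class = "dispersion_table"
  )
}

#' @export
print.dispersion_table <- function(x, ...) {
  cat(sprintf("<dispersion_table> %s: %d samples, %g-%g nm, n in [%.3g, %.3g]\n",
              x$material_id, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm), min(x$n), max(x$n)))
  invisible(x)
}

#' Non-dispersive material
#'
#' Convenience constructor for a material with constant optical constants
#' spanning 200-1200 nm, e.g. the single-refractive-index tissue model.
#'
#' @param n real refractive index.
#' @param k extinction coefficient (default 0).
#' @param material_id label.
#' @return A `dispersion_table`.
#' @export
constant_dispersion <- function(n, k = 0, material_id = "constant") {
  dispersion_table(c(200, 1200), c(n, n), c(k, k), material_id)
}

#' Read a dispersion table from CSV
#'
#' Expects the header `wavelength_nm,n,k`.
#'
#' @param path CSV file path.
#' @param material_id label; defaults to the file name.
#' @return A `dispersion_table`.
#' @export
read_dispersion_csv <- function(path, material_id = NULL) {
  d <- utils::read.csv(path)
  need <- c("wavelength_nm", "n", "k")
  if (!all(need %in% names(d)))
    stop("dispersion CSV must have columns wavelength_nm,n,k")
  if (is.null(material_id))
    material_id <- sub("\\.csv$", "", basename(path))
  dispersion_table(d$wavelength_nm, d$n, d$k, material_id)
}

#' Bundled slide materials
#'
#' Loads one of the dispersion tables shipped with the package: `"si"`
#' (crystalline silicon substrate) or `"si3n4"` (PECVD silicon nitride
#' cavity layer). Both are smooth synthetic tables at literature-typical
#' values, bundled so the optical model is self-contained; `"air"` and
#' `"glass"` are non-dispersive conveniences.
#'
#' @param material one of `"si"`, `"si3n4"`, `"air"`, `"glass"`.
#' @return A `dispersion_table`.
#' @examples
#' nos_material("si3n4")
#' @export
nos_material <- function(material = c("si", "si3n4", "air", "glass")) {
  material <- match.arg(material)
  if (material == "air") return(constant_dispersion(1, 0, "air"))
  if (material == "glass") return(constant_dispersion(1.52, 0, "glass"))
  file <- sprintf("dispersion_%s_synthetic.csv", material)
  path <- system.file("extdata", file, package = "noscolor", mustWork = TRUE)
  read_dispersion_csv(path, material_id = material)
}

#' Interpolate a dispersion table to a wavelength grid
#'
#' Returns the complex refractive index at the requested wavelengths using
#' the convention n_tilde = n - i k (time dependence exp(+i omega t)); n and
#' k are each linearly interpolated between tabulated samples.
#'
#' @param table a `dispersion_table`.
#' @param wavelengths numeric wavelengths (nm), each inside the table span.
#' @return Complex vector n - i k, one element per wavelength.
#' @export
interpolate_dispersion <- function(table, wavelengths) {
  stopifnot(inherits(table, "dispersion_table"))
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) == 0L) stop("empty wavelength grid")
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1]) || any(wavelengths > rng[2]))
    stop(sprintf("wavelength outside dispersion span [%g, %g] nm for '%s'",
                 rng[1], rng[2], table$material_id))
  if (length(table$wavelength_nm) == 1L) {
    return(complex(real = rep(table$n, length(wavelengths)),
                   imaginary = rep(-table$k, length(wavelengths))))
  }
  n <- stats::approx(table$wavelength_nm, table$n, xout = wavelengths)$y
  k <- stats::approx(table$wavelength_nm, table$k, xout = wavelengths)$y
  complex(real = n, imaginary = -k)
}
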
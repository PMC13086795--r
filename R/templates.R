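# Rhodopsin absorbance templates and spectral-sensitivity construction.

#' Wavelength grid constructor
#'
#' Validated strictly increasing wavelength grid in nanometres. The default is
#' the monochromator scan grid, 300 to 700 nm in 5 nm steps.
#'
#' @param from,to,by grid limits and step in nm.
#' @param wavelengths optional explicit vector overriding `from`/`to`/`by`.
#' @return numeric vector of class `wavelength_grid`.
#' @export
wavelength_grid <- function(from = 300, to = 700, by = 5, wavelengths = NULL) {
  wl <- wavelengths %||% seq(from, to, by = by)
  if (any(!is.finite(wl))) stop("wavelengths must be finite")
  if (min(wl) < 200 || max(wl) > 800) stop("wavelengths must lie in [200, 800] nm")
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  structure(as.numeric(wl), class = "wavelength_grid")
}

#' Spectral sensitivity container
#'
#' @param wavelength wavelength grid (nm).
#' @param s relative sensitivity, normalized so `max(s) == 1` unless
#'   `normalize = FALSE`.
#' @param meta named list of metadata (cell id, elevation, true amplitudes...).
#' @param opponent flag set on spectra of isolated opponent units, which are
#'   the only spectra allowed to carry negative values.
#' @param normalize divide by `max(s)` (default TRUE).
#' @return object of class `spectral_sensitivity` (a list with `wavelength`,
#'   `s`, `meta`, `opponent`).
#' @export
spectral_sensitivity <- function(wavelength, s, meta = list(), opponent = FALSE,
                                 normalize = TRUE) {
  wavelength <- as.numeric(wavelength)
  s <- as.numeric(s)
  stopifnot(length(wavelength) == length(s))
  if (any(!is.finite(s))) stop("sensitivity values must be finite")
  if (!opponent && any(s < 0)) stop("negative sensitivity only allowed for opponent spectra")
  if (normalize) {
    m <- max(s)
    if (m <= 0) stop("cannot normalize: maximum sensitivity is not positive")
    s <- s / m
  }
  structure(list(wavelength = wavelength, s = s, meta = meta, opponent = opponent),
            class = "spectral_sensitivity")
}

#' @export
print.spectral_sensitivity <- function(x, ...) {
  cat(sprintf("<spectral_sensitivity> %d points, %g-%g nm, peak at %g nm%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$wavelength[which.max(x$s)],
              if (isTRUE(x$opponent)) " [opponent]" else ""))
  invisible(x)
}

# Raw A1 alpha-band template (Govardovskii-family closed form), un-normalized.
.alpha_band <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

.beta_band <- function(lambda, lambda_max) {
  lm_b <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  0.26 * exp(-((lambda - lm_b) / b)^2)
}

.template_raw <- function(lambda, lambda_max, beta_band) {
  s <- .alpha_band(lambda, lambda_max)
  if (beta_band) s <- s + .beta_band(lambda, lambda_max)
  s
}

#' Visual-pigment absorbance template
#'
#' Evaluates an A1 rhodopsin absorbance template (alpha band, optional beta
#' band) peak-normalized so the true maximum equals 1. The peak value is
#' located by continuous optimization, so on any evaluation grid all values
#' are <= 1 and the grid point nearest `lambda_max` is >= 0.999 on a 1 nm grid.
#'
#' @param lambda_max peak wavelength in nm, within [300, 620].
#' @param grid wavelengths (nm) on which to evaluate; any numeric vector
#'   accepted by [wavelength_grid()].
#' @param beta_band include the UV beta band? Off by default: the band only
#'   affects wavelengths below ~400 nm and the two-template decomposition is
#'   restricted to 400-600 nm.
#' @return a [spectral_sensitivity()] (already normalized; not renormalized to
#'   the grid maximum, so partial grids keep their true relative scale).
#' @export
template_absorbance <- function(lambda_max, grid = wavelength_grid(),
                                beta_band = FALSE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 300 || lambda_max > 620) {
    stop("lambda_max must be a single wavelength in [300, 620] nm")
  }
  grid <- wavelength_grid(wavelengths = as.numeric(grid))
  peak <- stats::optimize(function(l) .template_raw(l, lambda_max, beta_band),
                          lower = lambda_max - 40, upper = lambda_max + 40,
                          maximum = TRUE, tol = 1e-8)$objective
  s <- .template_raw(grid, lambda_max, beta_band) / peak
  spectral_sensitivity(grid, pmin(s, 1),
                       meta = list(lambda_max = lambda_max, beta_band = beta_band),
                       normalize = FALSE)
}

#' Compose a sensitivity curve from weighted templates
#'
#' Weighted sum of peak-normalized absorbance templates, renormalized so the
#' composed curve has maximum 1. The true amplitudes (and their ratio, for
#' two-component mixtures) are kept in `meta` for generator use; the ratio is
#' invariant under the renormalization.
#'
#' @param components list of `list(lambda_max=, amplitude=)` entries (or
#'   two-element numeric vectors `c(lambda_max, amplitude)`); amplitudes >= 0,
#'   at least one > 0.
#' @param grid evaluation wavelengths in nm.
#' @param beta_band include beta bands in the component templates.
#' @return a [spectral_sensitivity()] with `meta$amplitudes`,
#'   `meta$lambda_max` and, when exactly two components, `meta$true_ratio`
#'   (first amplitude / second amplitude).
#' @export
compose_sensitivity <- function(components, grid = wavelength_grid(),
                                beta_band = FALSE) {
  if (length(components) == 0) stop("at least one component required")
  comp <- lapply(components, function(ci) {
    if (is.numeric(ci) && length(ci) == 2) ci <- list(lambda_max = ci[1], amplitude = ci[2])
    stopifnot(is.list(ci), !is.null(ci$lambda_max), !is.null(ci$amplitude))
    ci
  })
  amps <- vapply(comp, function(ci) ci$amplitude, numeric(1))
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (all(amps == 0)) stop("all amplitudes are zero")
  grid <- wavelength_grid(wavelengths = as.numeric(grid))
  s <- rep(0, length(grid))
  for (i in seq_along(comp)) {
    s <- s + amps[i] * template_absorbance(comp[[i]]$lambda_max, grid, beta_band)$s
  }
  meta <- list(amplitudes = amps,
               lambda_max = vapply(comp, function(ci) ci$lambda_max, numeric(1)))
  if (length(comp) == 2) {
    meta$true_ratio <- if (amps[2] > 0) amps[1] / amps[2] else Inf
  }
  spectral_sensitivity(grid, s, meta = meta)
}

#' Export a sensitivity curve as a two-column CSV
#'
#' @param s a [spectral_sensitivity()].
#' @param path output file.
#' @export
write_sensitivity_csv <- function(s, path) {
  stopifnot(inherits(s, "spectral_sensitivity"))
  utils::write.csv(data.frame(wavelength_nm = s$wavelength, sensitivity = s$s),
                   path, row.names = FALSE)
  invisible(path)
}
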
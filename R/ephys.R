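# Electrophysiology pipeline: Hill (Naka-Rushton) fits, reverse Hill
# transformation of spectral and polarization scans, opponent-unit isolation.

#' Hill (Naka-Rushton) intensity-response function
#'
#' V(I) = Vmax * I^n / (I^n + K^n), the saturating relation between relative
#' stimulus intensity and peak membrane depolarization.
#'
#' @param intensity relative intensity on [0, 1] (1 = unattenuated beam;
#'   an attenuation of `od` optical-density units gives `10^(-od)`).
#' @param vmax saturated response amplitude (mV).
#' @param n Hill coefficient.
#' @param k half-saturating relative intensity.
#' @export
hill_response <- function(intensity, vmax, n, k) {
  vmax * intensity^n / (intensity^n + k^n)
}

#' Build an intensity run table
#'
#' @param od attenuation in optical density units (0 = brightest), strictly
#'   monotone; default 4 to 0 in 0.2 OD steps.
#' @param response_mv peak response per step (mV, >= 0).
#' @param wavelength_nm test wavelength.
#' @return data.frame of class `intensity_run`.
#' @export
intensity_run <- function(od = seq(4, 0, by = -0.2), response_mv,
                          wavelength_nm = NA_real_) {
  stopifnot(length(od) == length(response_mv))
  if (any(response_mv < 0)) stop("responses must be non-negative")
  d <- diff(od)
  if (!(all(d > 0) || all(d < 0))) stop("attenuation must be strictly monotone")
  structure(data.frame(od = od, response_mv = response_mv,
                       wavelength_nm = wavelength_nm),
            class = c("intensity_run", "data.frame"))
}

#' Fit the Hill function to an intensity run
#'
#' Least-squares fit of V(I) = Vmax I^n / (I^n + K^n) with I = 10^(-OD).
#' Vmax is profiled out analytically (it enters the model linearly for fixed
#' n and K) and the remaining two parameters are optimized by bounded
#' quasi-Newton within n in [0.5, 3], K in [1e-6, 1]; Vmax is constrained to
#' (max(V), 3 max(V)]. Started at n = 1 and K = the intensity at half-maximal
#' response.
#'
#' @param run an [intensity_run()] or data.frame with columns `od`,
#'   `response_mv`; at least 6 points.
#' @param noise_floor assumed response noise SD (mV); the maximal response
#'   must exceed 5x this floor.
#' @return object of class `hill_fit`: list with `vmax`, `n`, `k`, `rss`,
#'   `fitted`, `convergence`.
#' @export
fit_hill <- function(run, noise_floor = 0.5) {
  od <- run$od
  v <- run$response_mv
  if (length(v) < 6) stop("need at least 6 intensity steps")
  if (max(v) <= 5 * noise_floor) stop("maximal response below 5x the noise floor")
  intensity <- 10^(-od)
  vhi <- max(v)
  vmax_lo <- vhi * (1 + 1e-9)
  vmax_hi <- 3 * vhi

  profile_vmax <- function(n, k) {
    h <- intensity^n / (intensity^n + k^n)
    vm <- sum(v * h) / sum(h^2)
    min(max(vm, vmax_lo), vmax_hi)
  }
  rss_fun <- function(par) {
    n <- par[1]; k <- 10^par[2]
    vm <- profile_vmax(n, k)
    sum((v - hill_response(intensity, vm, n, k))^2)
  }
  # K0: intensity where the response first crosses half-max, by interpolation
  ord <- order(intensity)
  k0 <- tryCatch(stats::approx(v[ord], intensity[ord], xout = vhi / 2,
                               ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(intensity)
  k0 <- min(max(k0, 1e-6), 1)
  rss_clamped <- function(par) {
    rss_fun(c(min(max(par[1], 0.5), 3), min(max(par[2], -6), 0)))
  }
  stage1 <- stats::optim(c(1, log10(k0)), rss_fun, method = "L-BFGS-B",
                         lower = c(0.5, -6), upper = c(3, 0),
                         control = list(maxit = 500))
  # polish: L-BFGS-B line searches stall on (near-)zero-residual data.
  # Nelder-Mead may return code 10 (simplex degeneracy) at the optimum, so
  # restart once and only call it non-convergence if it is still descending.
  fit <- stats::optim(stage1$par, rss_clamped, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 2000))
  if (fit$convergence != 0) {
    fit2 <- stats::optim(fit$par, rss_clamped, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 2000))
    if (fit2$convergence != 0 &&
        fit$value - fit2$value > 1e-8 * max(fit2$value, 1e-12)) {
      stop(sprintf("Hill fit did not converge (optim code %d, rss %.4g -> %.4g)",
                   fit2$convergence, fit$value, fit2$value))
    }
    fit <- fit2
  }
  n <- min(max(fit$par[1], 0.5), 3)
  k <- 10^min(max(fit$par[2], -6), 0)
  vmax <- profile_vmax(n, k)
  if (vmax >= vmax_hi * (1 - 1e-9)) {
    stop(sprintf("Hill fit error: Vmax hit the upper bound %.3g mV (data max %.3g mV)",
                 vmax_hi, vhi))
  }
  structure(list(vmax = vmax, n = n, k = k, rss = fit$value,
                 fitted = hill_response(intensity, vmax, n, k),
                 convergence = fit$convergence),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Vmax = %.3f mV, n = %.3f, K = %.4g, rss = %.3g\n",
              x$vmax, x$n, x$k, x$rss))
  invisible(x)
}

#' Build a spectral scan table
#'
#' @param wavelength_nm wavelengths (nm).
#' @param response_mv peak response per wavelength (mV; negative =
#'   hyperpolarizing).
#' @param sweep sweep tag, "up" or "down" (recycled).
#' @param adaptation `NULL` for dark-adapted, else a list with
#'   `wavelengths` (nm of the adapting light(s)) and `intensity` (relative).
#' @return data.frame of class `spectral_scan` with an `adaptation` attribute.
#' @export
spectral_scan <- function(wavelength_nm, response_mv, sweep = "up",
                          adaptation = NULL) {
  stopifnot(length(wavelength_nm) == length(response_mv))
  d <- data.frame(wavelength_nm = wavelength_nm, response_mv = response_mv,
                  sweep = rep_len(sweep, length(wavelength_nm)))
  structure(d, class = c("spectral_scan", "data.frame"), adaptation = adaptation)
}

# Invert a vector of depolarizing responses through the Hill function.
# Returns raw (un-normalized) sensitivities with NA at excluded points.
.invert_responses <- function(r, wl, hp, saturation_frac = 0.98,
                              context = "scan") {
  s <- rep(NA_real_, length(r))
  if (any(r >= hp$vmax)) {
    stop(sprintf("saturation error: response >= Vmax at %g nm",
                 wl[which(r >= hp$vmax)[1]]))
  }
  sat <- r >= saturation_frac * hp$vmax
  if (any(sat)) {
    warning(sprintf("%s: %d response(s) above %.0f%% of Vmax excluded (e.g. %g nm)",
                    context, sum(sat), 100 * saturation_frac, wl[which(sat)[1]]))
  }
  neg <- r < 0
  if (any(neg)) {
    warning(sprintf("%s: %d hyperpolarizing response(s) excluded (polarity warning)",
                    context, sum(neg)))
  }
  ok <- !sat & !neg
  s[ok] <- (r[ok] / (hp$vmax - r[ok]))^(1 / hp$n)
  s
}

#' Reverse Hill transformation of a spectral scan
#'
#' Converts iso-quantal peak responses into relative spectral sensitivity:
#' s(lambda) = (r / (Vmax - r))^(1/n), then averages up/down sweeps per
#' wavelength on the sensitivity scale (the inversion is nonlinear, so
#' averaging voltages first would bias the result) and normalizes to max 1.
#' Responses at or above 98% of Vmax are excluded with a warning; responses
#' >= Vmax raise a saturation error naming the wavelength. Hyperpolarizing
#' (negative) responses are excluded with a polarity warning - use
#' [isolate_opponent_unit()] for those.
#'
#' @param scan a [spectral_scan()] (dark-adapted or adapted).
#' @param hp a [fit_hill()] result for the same cell.
#' @param saturation_frac responses above this fraction of Vmax are dropped.
#' @param meta metadata list forwarded to the result.
#' @return a [spectral_sensitivity()] on the scan's wavelength grid
#'   (wavelengths where every sweep was excluded are dropped).
#' @export
reverse_hill <- function(scan, hp, saturation_frac = 0.98, meta = list()) {
  stopifnot(inherits(hp, "hill_fit") || all(c("vmax", "n", "k") %in% names(hp)))
  raw <- .invert_responses(scan$response_mv, scan$wavelength_nm, hp,
                           saturation_frac, context = "reverse_hill")
  wl <- sort(unique(scan$wavelength_nm))
  s <- vapply(wl, function(w) {
    si <- raw[scan$wavelength_nm == w]
    if (all(is.na(si))) NA_real_ else mean(si, na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(s)
  if (!any(keep)) stop("no usable responses after exclusions")
  spectral_sensitivity(wl[keep], s[keep], meta = meta)
}

#' Build a polarization run table
#'
#' @param angle_deg e-vector angles in degrees (0 = horizontal, 90 =
#'   vertical/dorso-ventral), within [0, 360); at least 8 distinct angles
#'   covering >= 180 degrees.
#' @param response_mv peak response per angle (mV).
#' @param wavelength_nm test wavelength.
#' @return data.frame of class `polarization_run`.
#' @export
polarization_run <- function(angle_deg, response_mv, wavelength_nm = NA_real_) {
  stopifnot(length(angle_deg) == length(response_mv))
  if (any(angle_deg < 0 | angle_deg >= 360)) stop("angles must lie in [0, 360)")
  if (length(unique(angle_deg)) < 8) stop("need at least 8 distinct angles")
  if (diff(range(angle_deg)) < 180) stop("angles must cover at least 180 degrees")
  structure(data.frame(angle_deg = angle_deg, response_mv = response_mv,
                       wavelength_nm = wavelength_nm),
            class = c("polarization_run", "data.frame"))
}

#' Polarization sensitivity and microvillar class from a polarization run
#'
#' Responses are inverted through the Hill function to sensitivities, then
#' fit with s(phi) = c0 + c1 cos(2 (phi - phi_max)) (linear in
#' cos 2phi / sin 2phi, so the fit is exact least squares). The polarization
#' sensitivity ratio is PS = (c0 + c1) / (c0 - c1) and phi_max is reported
#' modulo 180 degrees. phi_max bins give the microvillar class: vertical for
#' phi_max in [67.5, 112.5), horizontal for [0, 22.5) or [157.5, 180),
#' diagonal otherwise. Flat profiles (c1/c0 < 0.05) are indeterminate with
#' PS = 1; nonphysical fits (c0 <= c1) are indeterminate with PS = NA.
#'
#' @param run a [polarization_run()].
#' @param hp a [fit_hill()] result for the same cell.
#' @return list of class `polarization_result` with `phi_max`, `ps`,
#'   `microvilli_class`, `c0`, `c1`.
#' @export
polarization_profile <- function(run, hp) {
  raw <- .invert_responses(run$response_mv, run$angle_deg, hp,
                           context = "polarization_profile")
  ok <- !is.na(raw)
  phi <- run$angle_deg[ok] * pi / 180
  s <- raw[ok]
  X <- cbind(1, cos(2 * phi), sin(2 * phi))
  beta <- unname(stats::lm.fit(X, s)$coefficients)
  c0 <- beta[1]
  c1 <- sqrt(beta[2]^2 + beta[3]^2)
  phi_max <- (atan2(beta[3], beta[2]) / 2 * 180 / pi) %% 180
  if (c0 <= c1) {
    res <- list(phi_max = phi_max, ps = NA_real_,
                microvilli_class = "indeterminate", c0 = c0, c1 = c1)
  } else if (c1 / c0 < 0.05) {
    res <- list(phi_max = NA_real_, ps = 1,
                microvilli_class = "indeterminate", c0 = c0, c1 = c1)
  } else {
    cls <- if (phi_max >= 67.5 && phi_max < 112.5) "vertical"
           else if (phi_max < 22.5 || phi_max >= 157.5) "horizontal"
           else "diagonal"
    res <- list(phi_max = phi_max, ps = (c0 + c1) / (c0 - c1),
                microvilli_class = cls, c0 = c0, c1 = c1)
  }
  structure(res, class = "polarization_result")
}

#' @export
print.polarization_result <- function(x, ...) {
  cat(sprintf("<polarization_result> phi_max = %s deg, PS = %s, class = %s\n",
              format(x$phi_max, digits = 4), format(x$ps, digits = 4),
              x$microvilli_class))
  invisible(x)
}

#' Isolate a colour-opponent unit from a chromatically adapted scan
#'
#' Under selective chromatic adaptation (e.g. a strong green background on a
#' green-excited, red-inhibited cell) the excitatory input is desensitized and
#' the scan shows hyperpolarizing responses driven by the opponent unit. Those
#' negative responses are sign-inverted and passed through the same reverse
#' Hill inversion (reusing the host cell's Hill parameters), yielding the
#' opponent unit's spectral sensitivity, normalized to max 1 and flagged
#' `opponent = TRUE`. Multi-band adaptation (e.g. green + blue) is supported
#' via the scan's `adaptation` attribute, which is recorded in the result.
#'
#' @param dark the dark-adapted [spectral_sensitivity()] of the host cell
#'   (used for grid consistency checks).
#' @param adapted_scan a [spectral_scan()] with non-NULL adaptation.
#' @param hp the host cell's [fit_hill()] result.
#' @return a [spectral_sensitivity()] with `opponent = TRUE`; positive
#'   (excitatory remnant) responses contribute zero sensitivity.
#' @export
isolate_opponent_unit <- function(dark, adapted_scan, hp) {
  adaptation <- attr(adapted_scan, "adaptation")
  if (is.null(adaptation)) stop("adapted_scan carries no adaptation attribute")
  if (inherits(dark, "spectral_sensitivity")) {
    # the dark sensitivity may have dropped wavelengths (polarity/saturation
    # exclusions), so require substantial overlap rather than identity
    wl_a <- unique(adapted_scan$wavelength_nm)
    if (length(intersect(wl_a, dark$wavelength)) < 0.5 * length(wl_a)) {
      stop("dark and adapted scans must share the wavelength grid")
    }
  }
  r <- adapted_scan$response_mv
  if (!any(r < 0)) {
    stop("empty-opponent error: no hyperpolarizing responses (cell not opponent or adaptation insufficient)")
  }
  inv <- pmax(-r, 0)  # inverted hyperpolarizations; excitatory remnants -> 0
  raw <- suppressWarnings(
    .invert_responses(inv, adapted_scan$wavelength_nm, hp,
                      context = "isolate_opponent_unit"))
  wl <- sort(unique(adapted_scan$wavelength_nm))
  s <- vapply(wl, function(w) {
    si <- raw[adapted_scan$wavelength_nm == w]
    if (all(is.na(si))) NA_real_ else mean(si, na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(s)
  spectral_sensitivity(wl[keep], s[keep],
                       meta = list(adaptation = adaptation),
                       opponent = TRUE)
}
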
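# Two-template spectral decomposition, ratio classification, UV-peak
# screening, and the dorso-ventral gradient profile.

#' Non-negative least squares fit of two absorbance templates
#'
#' Fits S(lambda) ~ A445 T(lambda; 445) + A545 T(lambda; 545) by non-negative
#' least squares over the fit window (default 400-600 nm). With two
#' coefficients the NNLS solution is exact in closed form: the unconstrained
#' solution if it is feasible, otherwise the better of the two
#' single-template fits with the other coefficient clamped at zero.
#'
#' @param s a [spectral_sensitivity()] (normalized).
#' @param window fit window in nm, default `c(400, 600)`.
#' @param peaks the two fixed template peak wavelengths, default
#'   `c(445, 545)`.
#' @param beta_band include beta bands in the fitted templates (default off:
#'   they only matter below 400 nm, outside the window).
#' @return object of class `template_fit`: `a445`, `a545`, `ratio`
#'   (= a445/a545, `Inf` when a545 is 0 and a445 > 0), `rss`, `n_points`.
#' @export
fit_two_templates <- function(s, window = c(400, 600), peaks = c(445, 545),
                              beta_band = FALSE) {
  stopifnot(inherits(s, "spectral_sensitivity"), length(window) == 2,
            length(peaks) == 2)
  inw <- s$wavelength >= window[1] & s$wavelength <= window[2]
  if (sum(inw) < 10) stop("data error: fewer than 10 wavelengths inside the fit window")
  wl <- s$wavelength[inw]
  y <- s$s[inw]
  t1 <- template_absorbance(peaks[1], wl, beta_band)$s
  t2 <- template_absorbance(peaks[2], wl, beta_band)$s

  g11 <- sum(t1 * t1); g22 <- sum(t2 * t2); g12 <- sum(t1 * t2)
  b1 <- sum(t1 * y); b2 <- sum(t2 * y)
  rss_of <- function(a1, a2) {
    sum(y^2) - 2 * a1 * b1 - 2 * a2 * b2 +
      a1^2 * g11 + a2^2 * g22 + 2 * a1 * a2 * g12
  }
  det <- g11 * g22 - g12^2
  a1 <- (b1 * g22 - b2 * g12) / det
  a2 <- (b2 * g11 - b1 * g12) / det
  if (a1 < 0 || a2 < 0) {
    # active-set: clamp each coefficient at zero in turn, keep the better fit
    c1 <- max(b1 / g11, 0)  # a2 = 0
    c2 <- max(b2 / g22, 0)  # a1 = 0
    if (rss_of(c1, 0) <= rss_of(0, c2)) { a1 <- c1; a2 <- 0 } else { a1 <- 0; a2 <- c2 }
  }
  if (a1 == 0 && a2 == 0) stop("degenerate-fit error: both amplitudes zero")
  ratio <- if (a2 > 0) a1 / a2 else Inf
  structure(list(a445 = a1, a545 = a2, ratio = ratio,
                 rss = max(rss_of(a1, a2), 0), n_points = length(wl)),
            class = "template_fit")
}

#' @export
print.template_fit <- function(x, ...) {
  cat(sprintf("<template_fit> A445 = %.4f, A545 = %.4f, ratio = %s, rss = %.4g (%d points)\n",
              x$a445, x$a545, format(x$ratio, digits = 4), x$rss, x$n_points))
  invisible(x)
}

#' Classify a red-inhibited cell from its A445/A545 amplitude ratio
#'
#' Applies the printed thresholds: ratio > 1.1 gives "Bg+R-" (blue-dominant),
#' 0.9 < ratio < 1.1 gives "BG+R-" (balanced), ratio < 0.9 gives "G+R-"
#' (green-dominant). Ratios exactly 0.9 or 1.1 fall in the middle class so
#' that the rule is a total partition.
#'
#' @param fit a [fit_two_templates()] result, or a bare numeric ratio.
#' @return one of `"Bg+R-"`, `"BG+R-"`, `"G+R-"`.
#' @export
classify_ratio <- function(fit) {
  ratio <- if (inherits(fit, "template_fit")) fit$ratio else fit
  stopifnot(is.numeric(ratio), length(ratio) >= 1)
  vapply(ratio, function(r) {
    if (is.na(r) || r < 0) stop("ratio must be a non-negative number")
    if (r > 1.1) "Bg+R-" else if (r < 0.9) "G+R-" else "BG+R-"
  }, character(1))
}

#' Detect a secondary UV sensitivity peak
#'
#' Red-inhibited cells occasionally carry a second sensitivity peak in the UV
#' (U + L co-expression); such cells are excluded from class averages and
#' gradient statistics. A UV peak is called when a local maximum within
#' [300, 400) nm reaches at least `theta_uv` of the global maximum.
#'
#' @param s a [spectral_sensitivity()] whose grid covers 300-400 nm.
#' @param theta_uv relative-height threshold (default 0.6; the criterion is
#'   not quantified in the source protocol, so it is exposed here).
#' @return logical.
#' @export
detect_uv_peak <- function(s, theta_uv = 0.6) {
  stopifnot(inherits(s, "spectral_sensitivity"))
  wl <- s$wavelength
  if (min(wl) > 300 || max(wl) < 400) stop("coverage error: grid must cover 300-400 nm")
  y <- s$s
  n <- length(y)
  # local maxima: strictly above one neighbour, not below the other
  is_max <- rep(FALSE, n)
  for (i in seq_len(n)) {
    left <- if (i > 1) y[i - 1] else -Inf
    right <- if (i < n) y[i + 1] else -Inf
    is_max[i] <- y[i] >= left && y[i] >= right && (y[i] > left || y[i] > right)
  }
  uv <- is_max & wl >= 300 & wl < 400
  any(uv & y >= theta_uv * max(y))
}

#' Build a cell record for gradient analysis
#'
#' @param cell_id identifier.
#' @param elevation elevation in degrees (negative = ventral).
#' @param fit a [fit_two_templates()] result.
#' @param uv_peak logical from [detect_uv_peak()].
#' @param microvilli_class optional polarization class.
#' @return one-row data.frame of class `cell_record`.
#' @export
cell_record <- function(cell_id, elevation, fit, uv_peak = FALSE,
                        microvilli_class = NA_character_) {
  stopifnot(inherits(fit, "template_fit"))
  structure(data.frame(cell_id = cell_id, elevation = elevation,
                       a445 = fit$a445, a545 = fit$a545, ratio = fit$ratio,
                       class_label = classify_ratio(fit), uv_peak = uv_peak,
                       microvilli_class = microvilli_class),
            class = c("cell_record", "data.frame"))
}

#' Dorso-ventral gradient profile of the blue/green amplitude ratio
#'
#' Summarizes the A445/A545 ratio per elevation bin (mean, SD, n, majority
#' class) and tests for a monotone trend with Spearman rank correlation of
#' ratio against elevation, with a seeded permutation p-value. UV-peaking
#' cells must already be excluded (they are dropped here with a message if
#' present). The sign convention follows the elevation axis: a negative
#' correlation means the blue weight decreases dorsally.
#'
#' @param cells data.frame with columns `ratio`, `elevation` and optionally
#'   `uv_peak` (rows with `uv_peak == TRUE` are dropped).
#' @param bins elevation bin edges in degrees; the default
#'   `c(-90, -20, 10, 90)` gives ventral / equatorial (-20 to +10) / dorsal.
#' @param n_perm number of permutations for the p-value.
#' @param seed RNG seed for the permutation test.
#' @return list of class `gradient_profile` with `bins` (per-bin data.frame),
#'   `rho`, `p_perm`, `n`, `seed`.
#' @export
gradient_profile <- function(cells, bins = c(-90, -20, 10, 90),
                             n_perm = 10000, seed = 1L) {
  stopifnot(all(c("ratio", "elevation") %in% names(cells)))
  if ("uv_peak" %in% names(cells) && any(cells$uv_peak)) {
    message(sprintf("dropping %d UV-peaking cell(s) from the gradient analysis",
                    sum(cells$uv_peak)))
    cells <- cells[!cells$uv_peak, , drop = FALSE]
  }
  cells <- cells[is.finite(cells$ratio), , drop = FALSE]
  bin_idx <- cut(cells$elevation, breaks = bins, include.lowest = TRUE)
  if (length(unique(stats::na.omit(bin_idx))) < 2) {
    stop("trend undefined error: need at least 2 non-empty elevation bins")
  }
  per_bin <- do.call(rbind, lapply(levels(bin_idx), function(lv) {
    r <- cells$ratio[which(bin_idx == lv)]
    data.frame(bin = lv, n = length(r),
               mean_ratio = if (length(r)) mean(r) else NA_real_,
               sd_ratio = if (length(r) > 1) stats::sd(r) else NA_real_,
               majority_class = if (length(r)) names(which.max(table(classify_ratio(r)))) else NA_character_)
  }))
  rho <- stats::cor(cells$ratio, cells$elevation, method = "spearman")
  set.seed(seed)
  rperm <- replicate(n_perm,
                     stats::cor(sample(cells$ratio), cells$elevation,
                                method = "spearman"))
  p_perm <- (1 + sum(abs(rperm) >= abs(rho))) / (n_perm + 1)
  structure(list(bins = per_bin, rho = rho, p_perm = p_perm,
                 n = nrow(cells), seed = seed),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient_profile> n = %d cells, Spearman rho = %.3f, permutation p = %.4g\n",
              x$n, x$rho, x$p_perm))
  print(x$bins, row.names = FALSE)
  invisible(x)
}
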
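# Seeded synthetic-data generator: electrophysiology, mosaic sections and
# eyeshine stacks with ground truth, emulating the statistical structure the
# analysis pipeline assumes.

#' Generator configuration
#'
#' Defaults encode the stated world the generator emulates: responses follow
#' a Naka-Rushton nonlinearity (Vmax ~ 40 mV, n ~ 1, K ~ 0.1 on the relative
#' intensity scale 10^(-OD)); the blue/green amplitude ratio of red-inhibited
#' R1&2 and the red-ommatidium probability follow dorso-ventral logistics with
#' midpoint -5 deg (inside the equatorial band) and slope 15 deg; opponency is
#' post-nonlinearity subtraction with weight 0.3; the eyeshine red-fraction
#' endpoints are 0.1 (dorsal) and 0.6 (ventral); mosaics live on a hexagonal
#' lattice. Any component can be overridden via `...` (recursively merged).
#'
#' @param seed integer seed; identical config + seed reproduce identical
#'   outputs.
#' @param ... named components merged over the defaults (e.g.
#'   `noise = list(response_sd_mv = 0)`).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    hill = list(vmax_mean = 40, vmax_sd = 4, n_mean = 1, n_sd = 0.1,
                k_meanlog = log(0.1), k_sdlog = 0.2),
    noise = list(response_sd_mv = 0.5, spectral_sd = 0.03, label_sd = 0.1,
                 label_bg_sd = 0.05),
    gradient = list(
      ratio = list(r_min = 0.2, r_max = 1.6, e0 = -5, s = 15, jitter_sd = 0.05),
      bl = list(p_min = 0.05, p_max = 0.8, e0 = -5, s = 15),
      l = list(p_min = 0.1, p_max = 0.6, e0 = -5, s = 15),
      red = list(p_min = 0.1, p_max = 0.6, e0 = -5, s = 15)),
    opponency = list(w = 0.3, blue_w = 0.15, r9_cuton = 600, r9_edge = 10,
                     dorsal_blue_above = 10),
    stimulus = list(i0_frac = 0.7, adapt_intensity = 50, ps = 2),
    mosaic = list(rows = 40, cols = 50, spacing = 10, q_l = 0.7, p_ul = 0.03,
                  u_vs_b = 0.5, elevation_range = c(-60, 60)),
    lattice = list(rows = 14, cols = 16, spacing = 12, p_dark = 0.05,
                   spot_sigma_frac = 0.25, amp_range = c(0.7, 1),
                   glint_amp = 0.3, noise_sd = 0.05, bg_amp = 0.3)
  )
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  if (cfg$opponency$w < 0 || cfg$opponency$w >= 1) {
    stop("config error: opponency weight w must lie in [0, 1)")
  }
  for (g in cfg$gradient[c("bl", "l", "red")]) {
    if (!(g$p_min >= 0 && g$p_min <= g$p_max && g$p_max <= 1)) {
      stop("config error: gradient probabilities need 0 <= p_min <= p_max <= 1")
    }
  }
  structure(cfg, class = c("generator_config", "list"))
}

# Spectral sensitivity of the basal R9 red receptor: a 545 nm template seen
# through a long-pass red screening pigment (logistic cut-on edge).
r9_sensitivity <- function(grid, cuton = 600, edge = 10) {
  t545 <- template_absorbance(545, grid)$s
  screen <- 1 / (1 + exp(-(as.numeric(grid) - cuton) / edge))
  spectral_sensitivity(grid, t545 * screen)
}

# Evaluate a unit's sensitivity at arbitrary wavelengths (linear interp).
.sens_at <- function(s, wl) {
  stats::approx(s$wavelength, s$s, xout = wl, rule = 2)$y
}

# Weber-type adaptation gain for a unit under (possibly multi-band)
# background light: 1 / (1 + sum_a I_a * S_unit(lambda_a) / K).
.adapt_gain <- function(unit, adaptation, k) {
  if (is.null(adaptation)) return(1)
  drive <- sum(adaptation$intensity * .sens_at(unit, adaptation$wavelengths))
  1 / (1 + drive / k)
}

#' Simulate one photoreceptor's recording session
#'
#' Generates the full per-cell record: an intensity run at the peak
#' wavelength, dark-adapted up/down spectral sweeps, optional chromatically
#' adapted sweeps, and a polarization run, all from a known ground truth.
#' The response model is post-nonlinearity subtractive opponency,
#' r(lambda) = Hill(I0 g_e S_exc) - w Hill(I0 g_i S_inh), with Weber-type
#' adaptation gains g; the excitatory spectrum of red-inhibited R1&2 is a
#' 445+545 template mixture whose amplitude ratio follows the elevation
#' logistic; dorsal green cells get an extra blue (445 nm) inhibitory unit;
#' Y cells (red-shifted R5-8) receive the R9 red unit with positive sign.
#'
#' @param config a [generator_config()].
#' @param type one of `"U+G-"`, `"B+G-"`, `"Bg+R-"`, `"BG+R-"`, `"G+R-"`,
#'   `"Y"`, `"G"` (non-opponent green).
#' @param elevation elevation in degrees within [-90, 90].
#' @param adaptations list of adaptation specs, each
#'   `list(wavelengths =, intensity =)`, for which adapted scans are emitted;
#'   default a single strong green (550 nm) background.
#' @param seed seed for this cell; defaults to `config$seed`.
#' @return list with `intensity_run`, `dark_scan`, `adapted_scans` (named
#'   list of [spectral_scan()]), `polarization_run` and `truth` (hill
#'   parameters, true ratio, phi_max, unit spectra, R9 peak wavelength).
#' @export
simulate_cell <- function(config, type, elevation = 0,
                          adaptations = list(list(wavelengths = 550,
                                                  intensity = config$stimulus$adapt_intensity)),
                          seed = config$seed) {
  types <- c("U+G-", "B+G-", "Bg+R-", "BG+R-", "G+R-", "Y", "G")
  type <- match.arg(type, types)
  if (elevation < -90 || elevation > 90) stop("elevation must lie in [-90, 90]")
  set.seed(seed)
  grid <- wavelength_grid()
  op <- config$opponency

  vmax <- max(10, stats::rnorm(1, config$hill$vmax_mean, config$hill$vmax_sd))
  n <- min(max(stats::rnorm(1, config$hill$n_mean, config$hill$n_sd), 0.6), 2.5)
  k <- min(stats::rlnorm(1, config$hill$k_meanlog, config$hill$k_sdlog), 0.9)

  true_ratio <- NA_real_
  inh_units <- list()
  sign_inh <- -1
  w <- op$w
  phi_max <- 90
  if (type %in% c("U+G-", "B+G-")) {
    lm <- if (type == "U+G-") 355 else 445
    exc <- template_absorbance(lm, grid, beta_band = TRUE)
    inh_units <- list(green = template_absorbance(545, grid))
  } else if (type %in% c("Bg+R-", "BG+R-", "G+R-")) {
    g <- config$gradient$ratio
    true_ratio <- logistic_gradient(elevation, g$r_min, g$r_max, g$e0, g$s) *
      exp(stats::rnorm(1, 0, g$jitter_sd))
    exc <- compose_sensitivity(list(c(445, true_ratio), c(545, 1)), grid,
                               beta_band = TRUE)
    inh_units <- list(r9 = r9_sensitivity(grid, op$r9_cuton, op$r9_edge))
    if (type == "G+R-" && elevation > op$dorsal_blue_above && op$blue_w > 0) {
      inh_units$blue <- template_absorbance(445, grid)
    }
  } else if (type == "Y") {
    exc <- template_absorbance(565, grid)
    inh_units <- list(r9 = r9_sensitivity(grid, op$r9_cuton, op$r9_edge))
    sign_inh <- +1  # R9 excites the red-shifted R5-8
    phi_max <- 45
  } else {  # non-opponent green
    exc <- template_absorbance(545, grid)
    w <- 0
    phi_max <- 0
  }
  inh_w <- if (length(inh_units)) {
    stats::setNames(c(w, if (length(inh_units) > 1) op$blue_w), names(inh_units))
  } else numeric(0)

  f <- config$stimulus$i0_frac
  i0 <- k * (f / (1 - f))^(1 / n)
  sd_r <- config$noise$response_sd_mv

  respond <- function(wl, adaptation = NULL) {
    ge <- .adapt_gain(exc, adaptation, k)
    r <- hill_response(i0 * ge * .sens_at(exc, wl), vmax, n, k)
    for (nm in names(inh_units)) {
      gi <- .adapt_gain(inh_units[[nm]], adaptation, k)
      r <- r + sign_inh * inh_w[[nm]] *
        hill_response(i0 * gi * .sens_at(inh_units[[nm]], wl), vmax, n, k)
    }
    r + stats::rnorm(length(wl), 0, sd_r)
  }

  peak_wl <- exc$wavelength[which.max(exc$s)]
  od <- seq(4, 0, by = -0.2)
  irun <- intensity_run(od, pmax(hill_response(10^(-od) * i0, vmax, n, k) +
                                   stats::rnorm(length(od), 0, sd_r), 0),
                        wavelength_nm = peak_wl)

  wl_up <- as.numeric(grid)
  dark_scan <- spectral_scan(c(wl_up, rev(wl_up)),
                             c(respond(wl_up), respond(rev(wl_up))),
                             sweep = rep(c("up", "down"), each = length(wl_up)))
  adapted_scans <- lapply(adaptations, function(ad) {
    spectral_scan(c(wl_up, rev(wl_up)),
                  c(respond(wl_up, ad), respond(rev(wl_up), ad)),
                  sweep = rep(c("up", "down"), each = length(wl_up)),
                  adaptation = ad)
  })
  names(adapted_scans) <- vapply(adaptations, function(ad) {
    paste0("adapt_", paste(ad$wavelengths, collapse = "+"))
  }, character(1))

  ps <- config$stimulus$ps
  ang <- seq(0, 345, by = 15)
  s_pol <- (1 + (ps - 1) * cos((ang - phi_max) * pi / 180)^2) / ps
  prun <- polarization_run(ang, pmax(hill_response(i0 * s_pol, vmax, n, k) +
                                       stats::rnorm(length(ang), 0, sd_r), 0),
                           wavelength_nm = peak_wl)

  r9_peak <- if (!is.null(inh_units$r9)) {
    fine <- seq(550, 700, by = 1)
    fine[which.max(.sens_at(inh_units$r9, fine))]
  } else NA_real_

  list(intensity_run = irun, dark_scan = dark_scan,
       adapted_scans = adapted_scans, polarization_run = prun,
       truth = list(type = type, elevation = elevation,
                    vmax = vmax, n = n, k = k, i0 = i0,
                    true_ratio = true_ratio, phi_max = phi_max, ps = ps,
                    w = w, sign_inh = sign_inh,
                    exc = exc, inh_units = inh_units, r9_peak = r9_peak))
}

#' Simulate red-inhibited cells along the dorso-ventral gradient
#'
#' Convenience wrapper for closed-loop gradient tests: draws `n_cells`
#' elevations uniformly over `elevation_range`, sets each cell's true
#' A445/A545 ratio from the elevation logistic (with multiplicative jitter),
#' composes the 445+545 spectrum and adds i.i.d. Gaussian spectral noise.
#'
#' @param config a [generator_config()]; `config$gradient$ratio` drives the
#'   gradient and `config$noise$spectral_sd` the additive noise.
#' @param n_cells number of cells.
#' @param elevation_range range of elevations sampled (degrees).
#' @param seed seed; defaults to `config$seed`.
#' @return list with `sensitivities` (list of [spectral_sensitivity()]) and
#'   `truth` data.frame (`cell_id`, `elevation`, `true_ratio`).
#' @export
simulate_ratio_cells <- function(config, n_cells = 60,
                                 elevation_range = c(-60, 60),
                                 seed = config$seed) {
  set.seed(seed)
  g <- config$gradient$ratio
  grid <- wavelength_grid()
  elev <- stats::runif(n_cells, elevation_range[1], elevation_range[2])
  ratio <- logistic_gradient(elev, g$r_min, g$r_max, g$e0, g$s) *
    exp(stats::rnorm(n_cells, 0, g$jitter_sd))
  sens <- lapply(seq_len(n_cells), function(i) {
    s <- compose_sensitivity(list(c(445, ratio[i]), c(545, 1)), grid)
    y <- pmax(s$s + stats::rnorm(length(grid), 0, config$noise$spectral_sd), 0)
    spectral_sensitivity(grid, y, meta = list(cell_id = i, elevation = elev[i]))
  })
  list(sensitivities = sens,
       truth = data.frame(cell_id = seq_len(n_cells), elevation = elev,
                          true_ratio = ratio))
}

#' Simulate an immunolabelled mosaic section
#'
#' Ommatidia sit on a hexagonal lattice whose y axis maps linearly onto the
#' configured elevation range (larger y = dorsal). Each ommatidium is first
#' assigned L-class membership from the elevation logistic `gradient$l`
#' (red/L ommatidia frequent ventrally); within an L ommatidium each R1&2
#' cell expresses L with probability `q_l` (conditioned on at least one),
#' and an L-expressing cell co-expresses B with the elevation-dependent
#' probability `gradient$bl` or U at the small constant rate `p_ul`.
#' Non-L-expressing cells are U or B with a fixed ratio. Label intensities
#' are state indicators with multiplicative noise plus background noise.
#'
#' @param config a [generator_config()]; `config$mosaic` sets lattice size,
#'   spacing and the state-draw parameters.
#' @param seed seed; defaults to `config$seed`.
#' @return list with `table` (raw intensity table as consumed by
#'   [call_section_states()]) and `truth` (id, x, y, elevation, true states,
#'   type and category).
#' @export
simulate_mosaic_section <- function(config, seed = config$seed) {
  m <- config$mosaic
  if (m$rows < 4 || m$cols < 4) stop("lattice must be at least 4x4")
  set.seed(seed)
  lat <- hex_lattice(m$rows, m$cols, m$spacing)
  n <- nrow(lat)
  yr <- range(lat$y)
  elev <- m$elevation_range[1] +
    (lat$y - yr[1]) / diff(yr) * diff(m$elevation_range)
  gl <- config$gradient$l
  gb <- config$gradient$bl
  p_l <- logistic_gradient(elev, gl$p_min, gl$p_max, gl$e0, gl$s)
  p_bl <- logistic_gradient(elev, gb$p_min, gb$p_max, gb$e0, gb$s)

  draw_nonl <- function() if (stats::runif(1) < m$u_vs_b) "U" else "B"
  draw_l_cell <- function(pbl) {
    u <- stats::runif(1)
    if (u < m$p_ul) "UL" else if (u < m$p_ul + (1 - m$p_ul) * pbl) "BL" else "L"
  }
  states <- matrix(NA_character_, n, 2)
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_l[i]) {
      repeat {
        expr_l <- stats::runif(2) < m$q_l
        if (any(expr_l)) break
      }
      states[i, ] <- vapply(expr_l, function(e) {
        if (e) draw_l_cell(p_bl[i]) else draw_nonl()
      }, character(1))
    } else {
      states[i, ] <- c(draw_nonl(), draw_nonl())
    }
  }
  truth <- ommatidium_table(seq_len(n), lat$x, lat$y, states[, 1], states[, 2])
  truth$elevation <- elev

  noisy <- function(ind) {
    pmax(ind * (1 + stats::rnorm(n, 0, config$noise$label_sd)) +
           abs(stats::rnorm(n, 0, config$noise$label_bg_sd)), 0)
  }
  ind <- function(cell, ch) {
    s <- states[, cell]
    as.numeric((ch == "u" & s %in% c("U", "UL")) |
                 (ch == "b" & s %in% c("B", "BL")) |
                 (ch == "l" & s %in% c("L", "UL", "BL")))
  }
  tab <- data.frame(id = seq_len(n), x_um = lat$x, y_um = lat$y,
                    r1_u = noisy(ind(1, "u")), r1_b = noisy(ind(1, "b")),
                    r1_l = noisy(ind(1, "l")), r2_u = noisy(ind(2, "u")),
                    r2_b = noisy(ind(2, "b")), r2_l = noisy(ind(2, "l")))
  list(table = tab, truth = truth)
}

#' Simulate a hyperspectral eyeshine stack
#'
#' Gaussian reflection spots on a hexagonal lattice. Each spot is dark with
#' probability `p_dark`, otherwise red with probability p_red(elevation)
#' (logistic `gradient$red`), so the configured marginals are
#' P(dark) = p_dark, P(red) = (1 - p_dark) p_red(e). Red spots reflect only
#' in the 675/653 nm frames, non-red spots in all seven, dark spots not at
#' all. Every lattice site additionally carries a corneal lens reflection
#' ("glint", amplitude `glint_amp`) in every frame including the
#' light-adapted backgrounds: this is the punctate imaging artefact the
#' background subtraction removes, and it is what makes dark ommatidia
#' visible as lattice positions. A smooth background (ramp + broad blob) is
#' added throughout, with i.i.d. Gaussian pixel noise per frame.
#'
#' @param config a [generator_config()]; `config$lattice` sets geometry,
#'   amplitudes and noise.
#' @param elevation elevation in degrees.
#' @param eye replicate identifier.
#' @param seed seed; defaults to `config$seed`.
#' @return list with `stack` (an [eyeshine_stack()]) and `truth`
#'   (id, row, col, label) plus the configured marginal probabilities.
#' @export
simulate_eyeshine_stack <- function(config, elevation, eye = "eye1",
                                    seed = config$seed) {
  lt <- config$lattice
  set.seed(seed)
  lat <- hex_lattice(lt$rows, lt$cols, lt$spacing)
  nr <- ceiling(max(lat$y) + lt$spacing)
  nc <- ceiling(max(lat$x) + lt$spacing)
  g <- config$gradient$red
  p_red <- logistic_gradient(elevation, g$p_min, g$p_max, g$e0, g$s)
  nsp <- nrow(lat)
  u <- stats::runif(nsp)
  label <- ifelse(u < lt$p_dark, "dark",
                  ifelse(u < lt$p_dark + (1 - lt$p_dark) * p_red, "red", "non-red"))
  amp <- stats::runif(nsp, lt$amp_range[1], lt$amp_range[2])
  amp[label == "dark"] <- 0
  sig <- lt$spot_sigma_frac * lt$spacing

  render_spots <- function(a) {
    img <- matrix(0, nr, nc)
    half <- ceiling(3 * sig)
    for (i in seq_len(nsp)) {
      if (a[i] == 0) next
      r0 <- lat$y[i]; c0 <- lat$x[i]
      rr <- max(1, floor(r0 - half)):min(nr, ceiling(r0 + half))
      cc <- max(1, floor(c0 - half)):min(nc, ceiling(c0 + half))
      img[rr, cc] <- img[rr, cc] +
        a[i] * exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sig^2))
    }
    img
  }
  ramp <- outer(seq(0, 1, length.out = nr), seq(0.5, 1, length.out = nc))
  blob <- exp(-(outer((seq_len(nr) - nr / 2)^2, (seq_len(nc) - nc / 2)^2, "+")) /
                (2 * (max(nr, nc) / 2)^2))
  bg <- lt$bg_amp * (0.6 * ramp + 0.4 * blob)
  # corneal lens reflection at every facet, present in eyeshine and
  # light-adapted frames alike (it is the artefact background subtraction
  # removes, and the cue by which dark ommatidia remain detectable)
  glints <- render_spots(rep(lt$glint_amp, nsp))

  frames <- list(); bg_frames <- list()
  for (w in .EYESHINE_WL) {
    a_w <- ifelse(label == "dark", 0,
                  ifelse(label == "red" & !(w %in% .R_CHANNEL_WL), 0, amp))
    frames[[as.character(w)]] <- render_spots(a_w) + glints + bg +
      matrix(stats::rnorm(nr * nc, 0, lt$noise_sd), nr, nc)
    bg_frames[[as.character(w)]] <- glints + bg +
      matrix(stats::rnorm(nr * nc, 0, lt$noise_sd), nr, nc)
  }
  stack <- eyeshine_stack(frames, bg_frames, elevation = elevation, eye = eye)
  list(stack = stack,
       truth = data.frame(id = seq_len(nsp), row = lat$y, col = lat$x,
                          label = label),
       p_red_configured = (1 - lt$p_dark) * p_red,
       p_dark_configured = lt$p_dark)
}
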
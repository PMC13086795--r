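test_that("fit_hill recovers exact parameters and honors the midpoint identity", {
  run <- exact_intensity_run(40, 1, 0.1)
  hp <- fit_hill(run)
  expect_equal(hp$vmax, 40, tolerance = 1e-6)
  expect_equal(hp$n, 1, tolerance = 1e-6)
  expect_equal(hp$k, 0.1, tolerance = 1e-6)

  # midpoint identity: V(K) = Vmax / 2
  expect_equal(hill_response(hp$k, hp$vmax, hp$n, hp$k), hp$vmax / 2)

  # non-unit Hill coefficient
  hp2 <- fit_hill(exact_intensity_run(25, 1.4, 0.03))
  expect_equal(c(hp2$vmax, hp2$n, hp2$k), c(25, 1.4, 0.03), tolerance = 1e-6)

  expect_error(fit_hill(intensity_run(seq(4, 3.2, by = -0.2),
                                      rep(10, 5))), "at least 6")
  expect_error(fit_hill(intensity_run(seq(4, 0, by = -0.2),
                                      rep(0.1, 21))), "noise floor")
})

test_that("fit_hill parameter recovery under 2% noise (100 seeded runs)", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    od <- seq(4, 0, by = -0.2)
    v <- hill_response(10^(-od), 40, 1, 0.1) * (1 + rnorm(21, 0, 0.02))
    hp <- fit_hill(intensity_run(od, pmax(v, 0)))
    c(n_err = abs(hp$n - 1), k_rel = abs(hp$k / 0.1 - 1))
  }, numeric(2))
  # tolerance frozen from the same Monte-Carlo design (max |n err| ~ 0.07)
  expect_lt(max(errs["n_err", ]), 0.1)
  expect_lt(median(errs["k_rel", ]), 0.05)
})

test_that("reverse_hill inverts algebraically and averages sweeps on the sensitivity scale", {
  hp <- list(vmax = 40, n = 1, k = 0.1)
  # r = Vmax/2 at one wavelength, Vmax/4 elsewhere -> s = 1 vs 1/3
  wl <- seq(400, 500, by = 10)
  r <- rep(10, length(wl)); r[wl == 450] <- 20
  s <- reverse_hill(spectral_scan(wl, r), hp)
  expect_equal(s$s[s$wavelength == 450], 1)
  expect_equal(unique(s$s[s$wavelength != 450]), 1 / 3, tolerance = 1e-12)

  # averaging contract: output equals the mean of single-sweep sensitivities
  set.seed(1)
  r_up <- runif(length(wl), 5, 30)
  r_dn <- r_up * (1 + rnorm(length(wl), 0, 0.05))
  sc <- spectral_scan(c(wl, rev(wl)), c(r_up, rev(r_dn)),
                      sweep = rep(c("up", "down"), each = length(wl)))
  s_both <- reverse_hill(sc, hp)
  # oracle: un-normalized per-sweep sensitivities computed directly
  su <- (r_up / (hp$vmax - r_up))^(1 / hp$n)
  sd_ <- (r_dn / (hp$vmax - r_dn))^(1 / hp$n)
  expected <- (su + sd_) / 2
  expect_equal(s_both$s, expected / max(expected), tolerance = 1e-12)

  # saturation guard and polarity warning
  expect_error(reverse_hill(spectral_scan(wl, c(45, r[-1])), hp), "saturation")
  expect_warning(reverse_hill(spectral_scan(wl, c(39.6, r[-1])), hp), "excluded")
  expect_warning(reverse_hill(spectral_scan(wl, c(-5, r[-1])), hp), "polarity")
})

test_that("reverse Hill round trip is the identity to 1e-9", {
  s_true <- compose_sensitivity(list(c(445, 1), c(545, 1)))
  vmax <- 40; n <- 1.2; k <- 0.1
  i0 <- k * (0.7 / 0.3)^(1 / n)
  r <- hill_response(i0 * s_true$s, vmax, n, k)
  s_rec <- reverse_hill(spectral_scan(s_true$wavelength, r),
                        list(vmax = vmax, n = n, k = k))
  expect_equal(s_rec$s, s_true$s, tolerance = 1e-9)
})

test_that("polarization profile recovers angle, PS and class", {
  hp <- list(vmax = 40, n = 1, k = 0.1)
  make_run <- function(phi_max, ps) {
    ang <- seq(0, 345, by = 15)
    s <- (1 + (ps - 1) * cos((ang - phi_max) * pi / 180)^2) / ps
    polarization_run(ang, hill_response(0.233 * s, hp$vmax, hp$n, hp$k))
  }
  res <- polarization_profile(make_run(90, 2), hp)
  expect_equal(res$phi_max, 90, tolerance = 2)
  expect_equal(res$ps, 2, tolerance = 0.05)
  expect_equal(res$microvilli_class, "vertical")

  expect_equal(polarization_profile(make_run(47, 2), hp)$microvilli_class,
               "diagonal")
  expect_equal(polarization_profile(make_run(0, 2), hp)$microvilli_class,
               "horizontal")

  # flat profile -> indeterminate, PS = 1
  flat <- polarization_run(seq(0, 345, by = 15), rep(15, 24))
  res_flat <- polarization_profile(flat, hp)
  expect_equal(res_flat$ps, 1)
  expect_equal(res_flat$microvilli_class, "indeterminate")

  # rotation equivariance (property): shifting angles shifts phi_max mod 180
  for (shift in c(20, 75, 130)) {
    ang <- seq(0, 345, by = 15)
    ps <- 3; phi0 <- 40
    s <- (1 + (ps - 1) * cos((ang - phi0) * pi / 180)^2) / ps
    r <- hill_response(0.233 * s, hp$vmax, hp$n, hp$k)
    base <- polarization_profile(polarization_run(ang, r), hp)$phi_max
    shifted <- polarization_profile(
      polarization_run((ang + shift) %% 360, r), hp)$phi_max
    expect_equal((base + shift) %% 180, shifted, tolerance = 1e-6)
  }
})

test_that("opponent-unit isolation recovers the inhibitory spectrum", {
  cfg <- quiet_config(seed = 21)
  cell <- simulate_cell(cfg, "G+R-", elevation = -30)
  hp <- fit_hill(cell$intensity_run)
  dark <- suppressWarnings(reverse_hill(cell$dark_scan, hp))
  opp <- isolate_opponent_unit(dark, cell$adapted_scans[[1]], hp)
  expect_true(opp$opponent)
  peak <- opp$wavelength[which.max(opp$s)]
  expect_lte(abs(peak - cell$truth$r9_peak), 10)

  # dorsal cell: green-only adaptation leaves a blue maximum, green+blue
  # adaptation removes it
  cell_d <- simulate_cell(cfg, "G+R-", elevation = 40, adaptations = list(
    list(wavelengths = 550, intensity = 50),
    list(wavelengths = c(550, 450), intensity = c(50, 50))))
  hp_d <- fit_hill(cell_d$intensity_run)
  dark_d <- suppressWarnings(reverse_hill(cell_d$dark_scan, hp_d))
  o_green <- isolate_opponent_unit(dark_d, cell_d$adapted_scans[[1]], hp_d)
  o_both <- isolate_opponent_unit(dark_d, cell_d$adapted_scans[[2]], hp_d)
  blue_max <- function(o) max(o$s[o$wavelength >= 400 & o$wavelength <= 500])
  red_max <- function(o) max(o$s[o$wavelength >= 580])
  expect_gt(blue_max(o_green), 0.5)   # blue inhibitory input visible
  expect_gt(red_max(o_green), 0.2)    # red input visible too (two maxima)
  expect_lt(blue_max(o_both), 0.2)    # double adaptation suppresses the blue

  # a cell without opponency yields the empty-opponent error
  cell_g <- simulate_cell(cfg, "G", elevation = 0)
  hp_g <- fit_hill(cell_g$intensity_run)
  dark_g <- reverse_hill(cell_g$dark_scan, hp_g)
  expect_error(isolate_opponent_unit(dark_g, cell_g$adapted_scans[[1]], hp_g),
               "empty-opponent")
  # and a dark scan carries no adaptation attribute
  expect_error(isolate_opponent_unit(dark_g, cell_g$dark_scan, hp_g),
               "adaptation")
})
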
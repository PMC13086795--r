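test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(seed = 123)
  a <- simulate_mosaic_section(cfg)
  b <- simulate_mosaic_section(cfg)
  expect_identical(a, b)

  e1 <- simulate_eyeshine_stack(cfg, elevation = -30)
  e2 <- simulate_eyeshine_stack(cfg, elevation = -30)
  expect_identical(e1, e2)

  c1 <- simulate_cell(cfg, "BG+R-", elevation = 0)
  c2 <- simulate_cell(cfg, "BG+R-", elevation = 0)
  expect_identical(c1, c2)

  # a different seed changes the draw
  expect_false(identical(a$table,
                         simulate_mosaic_section(cfg, seed = 124)$table))
})

test_that("config validation rejects nonphysical settings", {
  expect_error(generator_config(opponency = list(w = 1.2)), "w must lie")
  expect_error(generator_config(gradient = list(bl = list(p_min = 0.9, p_max = 0.1,
                                                          e0 = 0, s = 10))),
               "p_min <= p_max")
  cfg <- generator_config(mosaic = list(rows = 2, cols = 2))
  expect_error(simulate_mosaic_section(cfg), "4x4")
  expect_error(simulate_cell(generator_config(), "G+R-", elevation = 120),
               "elevation")
})

test_that("mosaic generator marginals follow the configured gradients", {
  cfg <- generator_config(seed = 77)
  sim <- simulate_mosaic_section(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 2000)
  # restricting to {U,B,L}: with p_bl = p_ul = 0 only the 6 basic types occur
  cfg0 <- generator_config(seed = 77,
                           gradient = list(bl = list(p_min = 0, p_max = 0,
                                                     e0 = -5, s = 15)),
                           mosaic = list(p_ul = 0))
  tr0 <- simulate_mosaic_section(cfg0)$truth
  expect_true(all(tr0$type_label %in%
                    c("U/U", "U/B", "B/B", "U/L", "B/L", "L/L")))
  expect_lte(length(unique(tr0$type_label)), 6)

  # L-ommatidium frequency tracks the logistic within the binomial envelope
  gl <- cfg$gradient$l
  for (band in list(c(-60, -30), c(-10, 10), c(30, 60))) {
    sel <- tr$elevation >= band[1] & tr$elevation <= band[2]
    p_hat <- mean(tr$category[sel] != "nonL")
    p_cfg <- mean(logistic_gradient(tr$elevation[sel], gl$p_min, gl$p_max,
                                    gl$e0, gl$s))
    expect_lt(abs(p_hat - p_cfg), 3 * sqrt(p_cfg * (1 - p_cfg) / sum(sel)) + 0.01)
  }
})

test_that("eyeshine generator marginals and degenerate settings", {
  # p_red = 1, p_dark = 0: every detected spot is classified red
  cfg1 <- generator_config(seed = 5,
                           gradient = list(red = list(p_min = 1, p_max = 1,
                                                      e0 = -5, s = 15)),
                           lattice = list(p_dark = 0))
  sim1 <- simulate_eyeshine_stack(cfg1, elevation = 0)
  det1 <- process_eyeshine_stack(sim1$stack, spacing = 12)
  expect_true(all(det1$label == "red"))

  # p_dark = 1: everything dark
  cfg2 <- generator_config(seed = 5, lattice = list(p_dark = 1))
  sim2 <- simulate_eyeshine_stack(cfg2, elevation = 0)
  det2 <- process_eyeshine_stack(sim2$stack, spacing = 12)
  expect_true(all(det2$label == "dark"))
  fp <- fraction_profile(det2)
  expect_equal(fp$per_image$f_dark, 1)

  # generator truth marginal within binomial CI of the configured value
  cfg3 <- generator_config(seed = 6)
  sim3 <- simulate_eyeshine_stack(cfg3, elevation = -90)
  p_cfg <- sim3$p_red_configured
  n <- nrow(sim3$truth)
  expect_lt(abs(mean(sim3$truth$label == "red") - p_cfg),
            3 * sqrt(p_cfg * (1 - p_cfg) / n))
})

test_that("simulated cells honour their construction contracts", {
  cfg <- quiet_config(seed = 9)
  # w = 0: no negative responses under any adaptation
  cell <- simulate_cell(cfg, "G", elevation = 0)
  expect_true(all(cell$dark_scan$response_mv >= 0))
  expect_true(all(cell$adapted_scans[[1]]$response_mv >= 0))

  # U cell peaks in the UV and is vertically polarized
  cu <- simulate_cell(cfg, "U+G-", elevation = 0)
  hp <- fit_hill(cu$intensity_run)
  s <- suppressWarnings(reverse_hill(cu$dark_scan, hp))
  pk <- s$wavelength[which.max(s$s)]
  expect_gte(pk, 340); expect_lte(pk, 360)
  expect_equal(polarization_profile(cu$polarization_run, hp)$microvilli_class,
               "vertical")

  # Y cells receive the red unit with positive sign: green adaptation
  # leaves a positive red response, never a hyperpolarization
  cy <- simulate_cell(cfg, "Y", elevation = 0)
  ad <- cy$adapted_scans[[1]]
  expect_true(all(ad$response_mv > -1e-9))
  red_part <- ad$response_mv[ad$wavelength_nm >= 620]
  expect_gt(max(red_part), 1)
  expect_error(isolate_opponent_unit(
    suppressWarnings(reverse_hill(cy$dark_scan, fit_hill(cy$intensity_run))),
    ad, fit_hill(cy$intensity_run)), "empty-opponent")

  # true ratio follows the elevation logistic
  g <- cfg$gradient$ratio
  cv <- simulate_cell(generator_config(seed = 10,
                                       gradient = list(ratio = list(
                                         r_min = 0.2, r_max = 1.6, e0 = -5,
                                         s = 15, jitter_sd = 0))),
                      "Bg+R-", elevation = -50)
  expect_equal(cv$truth$true_ratio,
               logistic_gradient(-50, 0.2, 1.6, -5, 15), tolerance = 1e-12)
})
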
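# Analytic image fixtures.
make_spot_image <- function(nr, nc, centers, amp = 1, sigma = 3) {
  img <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-(outer((seq_len(nr) - centers$row[i])^2,
                                   (seq_len(nc) - centers$col[i])^2, "+")) /
                             (2 * sigma^2))
  }
  img
}

test_that("background subtraction removes smooth artefacts and clips", {
  nr <- 40; nc <- 50
  grad <- outer(seq(0, 1, length.out = nr), seq(0, 1, length.out = nc))
  centers <- data.frame(row = c(12, 28), col = c(15, 38))
  spots <- make_spot_image(nr, nc, centers)
  frames <- list("675" = spots + grad, "653" = grad * 0.5)
  bgs <- list("675" = grad, "653" = grad)
  st <- eyeshine_stack(frames, bgs)
  cl <- subtract_background(st, sigma = 1)
  # self-subtraction channel: ~0 everywhere, negatives clipped
  expect_true(all(cl$frames[["653"]] >= 0))
  expect_lt(max(cl$frames[["653"]]), 0.02)
  # spot channel: spots retained, gradient removed
  expect_gt(cl$frames[["675"]][12, 15], 0.9)
  corner_resid <- max(cl$frames[["675"]][35:40, 1:5])
  expect_lt(corner_resid, 0.02 * max(spots))

  bad <- st; bad$background_frames[["675"]] <- matrix(0, 2, 2)
  expect_error(subtract_background(bad), "shape mismatch")
})

test_that("RGB mapping takes per-channel medians and validates wavelengths", {
  nr <- 5; nc <- 4
  mk <- function(v) matrix(v, nr, nc)
  frames <- list("675" = mk(2), "653" = mk(4), "635" = mk(1), "622" = mk(3),
                 "610" = mk(5), "594" = mk(7), "575" = mk(100))
  st <- eyeshine_stack(frames, lapply(frames, function(f) f * 0))
  rgb <- map_to_rgb(st)
  expect_true(all(rgb$R == 3))          # median of {2, 4}
  expect_true(all(rgb$G == 4))          # median of {1, 3, 5, 7} = mean(3, 5)
  expect_true(all(rgb$B == 0))
  # 575 nm is ingested but not mapped (the value 100 never leaks through)
  expect_false(any(rgb$R == 100) || any(rgb$G == 100))

  st2 <- eyeshine_stack(frames[c("675", "635", "622", "610", "594")],
                        lapply(frames[c("675", "635", "622", "610", "594")],
                               function(f) f * 0))
  expect_error(map_to_rgb(st2), "653")
})

test_that("detector finds a clean lattice exactly and handles blanks", {
  lat <- hex_lattice <- expand.grid(r = seq(10, 110, by = 12),
                                    c = seq(10, 150, by = 12))
  centers <- data.frame(row = lat$r, col = lat$c)
  img <- make_spot_image(120, 160, centers, sigma = 3)
  det <- detect_ommatidia(img, spacing = 12)
  expect_equal(nrow(det), nrow(centers))
  m <- match_detections(det, centers, tol = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  expect_warning(d0 <- detect_ommatidia(matrix(0, 50, 50), spacing = 12),
                 "noise floor")
  expect_equal(nrow(d0), 0)
})

test_that("detector recall/precision >= 0.98 at 5% noise (seeded)", {
  set.seed(31)
  lat <- expand.grid(r = seq(10, 110, by = 12), c = seq(10, 150, by = 12))
  centers <- data.frame(row = lat$r, col = lat$c)
  img <- make_spot_image(120, 160, centers, sigma = 3) +
    matrix(rnorm(120 * 160, 0, 0.05), 120, 160)
  det <- detect_ommatidia(img, spacing = 12)
  m <- match_detections(det, centers, tol = 2)
  expect_gte(m$recall, 0.98)
  expect_gte(m$precision, 0.98)
})

test_that("classification thresholds, ratio invariance and dark percentile", {
  nr <- 60; nc <- 60
  centers <- data.frame(row = c(15, 15, 45, 45), col = c(15, 45, 15, 45))
  # spot 1: pure red; spot 2: balanced; spot 3: dim (dark); spot 4: bright red
  R <- make_spot_image(nr, nc, centers[c(1, 4), ]) +
    make_spot_image(nr, nc, centers[2, , drop = FALSE], amp = 0.5) +
    make_spot_image(nr, nc, centers[3, , drop = FALSE], amp = 0.02)
  G <- make_spot_image(nr, nc, centers[2, , drop = FALSE], amp = 0.5) +
    make_spot_image(nr, nc, centers[3, , drop = FALSE], amp = 0.02)
  rgb <- structure(list(R = R, G = G, B = R * 0), class = "rgb_image")
  cl <- classify_ommatidia(centers, rgb, spacing = 12)
  expect_equal(as.character(cl$label), c("red", "non-red", "dark", "red"))
  expect_equal(cl$redness[1], 1, tolerance = 0.05)
  expect_equal(cl$redness[2], 0.5, tolerance = 0.05)

  # uniform scaling of both channels leaves every label unchanged (redness is
  # a ratio and the dark threshold rescales with the image percentile)
  rgb2 <- structure(list(R = R * 7, G = G * 7, B = R * 0), class = "rgb_image")
  cl2 <- classify_ommatidia(centers, rgb2, spacing = 12)
  expect_equal(as.character(cl2$label), as.character(cl$label))
  expect_equal(cl2$redness, cl$redness, tolerance = 1e-12)

  # but dark calls are relative to the image's own percentile: dimming one
  # spot while the rest of the image stays flips it to dark
  R3 <- R; G3 <- G
  sel_r <- 8:22; sel_c <- 38:52   # around spot 2 at (15, 45)
  R3[sel_r, sel_c] <- R3[sel_r, sel_c] * 0.05
  G3[sel_r, sel_c] <- G3[sel_r, sel_c] * 0.05
  cl3 <- classify_ommatidia(centers, structure(list(R = R3, G = G3, B = R * 0),
                                               class = "rgb_image"),
                            spacing = 12)
  expect_equal(as.character(cl3$label)[2], "dark")

  # centers outside the image are skipped with a warning
  expect_warning(
    cl4 <- classify_ommatidia(rbind(centers, data.frame(row = 500, col = 5)),
                              rgb, spacing = 12), "outside")
  expect_equal(nrow(cl4), 4)
})

test_that("fraction profile arithmetic and replicate averaging", {
  det <- data.frame(
    elevation = rep(0, 100), eye = "e1",
    label = factor(rep(c("red", "non-red"), c(60, 40)),
                   levels = c("red", "non-red", "dark")))
  fp <- fraction_profile(det)
  expect_equal(fp$per_image$f_red, 0.6)
  expect_equal(fp$per_image$f_nonred, 0.4)
  expect_equal(fp$per_image$f_dark, 0)
  expect_equal(fp$per_image$f_red + fp$per_image$f_nonred + fp$per_image$f_dark, 1)

  det2 <- rbind(det,
                data.frame(elevation = 0, eye = "e2",
                           label = factor(rep(c("red", "non-red"), c(70, 30)),
                                          levels = c("red", "non-red", "dark"))))
  fp2 <- fraction_profile(det2)
  expect_equal(fp2$per_elevation$f_red, 0.65)
  expect_equal(fp2$per_elevation$sd_red, sd(c(0.6, 0.7)))
  expect_equal(fp2$per_elevation$sd_red, 0.0707107, tolerance = 1e-6)
})

test_that("recovered red fraction declines dorsally whenever p_red does", {
  # scaled-down multi-seed suite (small lattice, 5 elevations, 10 seeds) of
  # the end-to-end monotonicity property
  n_neg <- 0
  for (seed in 1:10) {
    cfg <- generator_config(seed = seed, lattice = list(rows = 8, cols = 8))
    f_red <- vapply(seq(-90, 90, by = 45), function(e) {
      sim <- simulate_eyeshine_stack(cfg, elevation = e,
                                     seed = cfg$seed * 100L + e)
      det <- process_eyeshine_stack(sim$stack, spacing = 12)
      mean(det$label == "red")
    }, numeric(1))
    rho <- cor(seq(-90, 90, by = 45), f_red, method = "spearman")
    n_neg <- n_neg + (rho < 0)
  }
  expect_gte(n_neg, 9)
})
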
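# Hyperspectral eyeshine analysis: background subtraction, RGB mapping,
# lattice spot detection, red / non-red / dark classification, and
# dorso-ventral fraction profiles.

.EYESHINE_WL <- c(675, 653, 635, 622, 610, 594, 575)
.R_CHANNEL_WL <- c(675, 653)
.G_CHANNEL_WL <- c(635, 622, 610, 594)

#' Eyeshine stack container
#'
#' One elevation's worth of monochromatic dark-adapted eyeshine frames plus
#' the matching light-adapted background frames.
#'
#' @param frames named list of numeric matrices; names are wavelengths in nm.
#' @param background_frames named list matching `frames` in names and shape.
#' @param elevation elevation angle in degrees (negative = ventral).
#' @param eye replicate (eye) identifier.
#' @return object of class `eyeshine_stack`.
#' @export
eyeshine_stack <- function(frames, background_frames, elevation = NA_real_,
                           eye = "eye1") {
  stopifnot(is.list(frames), is.list(background_frames),
            length(frames) == length(background_frames))
  wl <- as.numeric(names(frames))
  if (any(is.na(wl)) || anyDuplicated(wl)) {
    stop("frames must be named by unique numeric wavelengths (nm)")
  }
  dims <- unique(lapply(c(frames, background_frames), dim))
  if (length(dims) != 1) stop("data error: all frames must share dimensions")
  structure(list(frames = frames,
                 background_frames = background_frames[names(frames)],
                 wavelengths = wl, elevation = elevation, eye = eye),
            class = "eyeshine_stack")
}

#' @export
print.eyeshine_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<eyeshine_stack> elevation %g deg, eye %s, %d wavelengths (%s nm), %dx%d px\n",
              x$elevation, x$eye, length(x$wavelengths),
              paste(x$wavelengths, collapse = ", "), d[1], d[2]))
  invisible(x)
}

#' Subtract smoothed background frames from an eyeshine stack
#'
#' Per wavelength, the light-adapted background frame is Gaussian-filtered
#' (default sigma = 1 px) and subtracted from its dark-adapted counterpart;
#' negative differences are clipped at zero. This removes smooth imaging
#' artefacts such as internal lens reflections while preserving the point-like
#' ommatidial reflections.
#'
#' @param stack an [eyeshine_stack()].
#' @param sigma Gaussian filter SD in pixels.
#' @return the stack with cleaned `frames` (backgrounds kept for reference).
#' @export
subtract_background <- function(stack, sigma = 1) {
  stopifnot(inherits(stack, "eyeshine_stack"))
  cleaned <- lapply(names(stack$frames), function(nm) {
    f <- stack$frames[[nm]]
    b <- stack$background_frames[[nm]]
    if (!identical(dim(f), dim(b))) stop("data error: frame/background shape mismatch")
    pmax(f - gaussian_blur(b, sigma), 0)
  })
  names(cleaned) <- names(stack$frames)
  stack$frames <- cleaned
  stack$cleaned <- TRUE
  stack
}

#' Map a cleaned eyeshine stack into RGB channels
#'
#' Pixelwise median of the 675 and 653 nm frames forms the R channel; the
#' median of the 635, 622, 610 and 594 nm frames forms the G channel. The
#' 575 nm frame, although acquired, is not mapped (kept only for QC). B is
#' zero by default or a copy of G+R rendering for white display.
#'
#' @param stack an [eyeshine_stack()] (ideally after
#'   [subtract_background()]).
#' @param r_wavelengths,g_wavelengths wavelength sets for the two channels.
#' @return list of class `rgb_image` with matrices `R`, `G`, `B`.
#' @export
map_to_rgb <- function(stack, r_wavelengths = .R_CHANNEL_WL,
                       g_wavelengths = .G_CHANNEL_WL) {
  stopifnot(inherits(stack, "eyeshine_stack"))
  missing_wl <- setdiff(c(r_wavelengths, g_wavelengths), stack$wavelengths)
  if (length(missing_wl)) {
    stop("configuration error: stack lacks wavelength(s) ",
         paste(missing_wl, collapse = ", "), " nm")
  }
  px_median <- function(wls) {
    mats <- stack$frames[as.character(wls)]
    arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    apply(arr, c(1, 2), stats::median)
  }
  R <- px_median(r_wavelengths)
  G <- px_median(g_wavelengths)
  structure(list(R = R, G = G, B = array(0, dim(R))), class = "rgb_image")
}

#' Detect ommatidial reflections on a lattice image
#'
#' Band-pass filtering by difference of Gaussians (sigma = spacing/4 and
#' spacing) followed by local-maximum extraction with greedy non-maximum
#' suppression at a minimum separation of 0.8 x spacing, and subpixel centroid
#' refinement over a spacing/2 window of the positive band-pass response.
#' Maxima must exceed `floor_frac` of the strongest band-pass response
#' (relative floor frozen from a seeded benchmark); if nothing exceeds the
#' floor an empty result is returned with a warning.
#'
#' @param image numeric matrix (typically `R + G` of [map_to_rgb()]).
#' @param spacing expected lattice spacing in pixels (>= 3).
#' @param floor_frac relative detection floor.
#' @return data.frame with columns `row`, `col` (subpixel centers) and
#'   `response`.
#' @export
detect_ommatidia <- function(image, spacing, floor_frac = 0.08) {
  stopifnot(is.matrix(image), spacing >= 3)
  dog <- gaussian_blur(image, spacing / 4) - gaussian_blur(image, spacing)
  mx <- max(dog)
  empty <- data.frame(row = numeric(0), col = numeric(0), response = numeric(0))
  if (mx <= 0) {
    warning("no maxima above noise floor; returning empty detection set")
    return(empty)
  }
  floor <- floor_frac * mx
  nr <- nrow(dog); nc <- ncol(dog)
  # 3x3 local maxima above the floor
  cand <- which(dog > floor, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 & cand[, 2] < nc, ,
               drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no maxima above noise floor; returning empty detection set")
    return(empty)
  }
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    v <- dog[r, c]
    all(v >= dog[(r - 1):(r + 1), (c - 1):(c + 1)])
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  vals <- dog[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  # greedy non-maximum suppression at 0.8 * spacing
  min_sep2 <- (0.8 * spacing)^2
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { sel[1] <- TRUE; next }
    prev <- which(sel[seq_len(i - 1)])
    d2 <- (cand[prev, 1] - cand[i, 1])^2 + (cand[prev, 2] - cand[i, 2])^2
    sel[i] <- all(d2 >= min_sep2)
  }
  cand <- cand[sel, , drop = FALSE]
  vals <- vals[sel]
  # subpixel centroid over a spacing/2 window of the positive response
  half <- max(1L, round(spacing / 4))
  centers <- t(vapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rr <- max(1, r0 - half):min(nr, r0 + half)
    cc <- max(1, c0 - half):min(nc, c0 + half)
    w <- pmax(dog[rr, cc, drop = FALSE], 0)
    sw <- sum(w)
    if (sw == 0) return(c(r0, c0))
    c(sum(outer(rr, rep(1, length(cc))) * w) / sw,
      sum(outer(rep(1, length(rr)), cc) * w) / sw)
  }, numeric(2)))
  data.frame(row = centers[, 1], col = centers[, 2], response = vals)
}

#' Classify detected ommatidia as red, non-red or dark
#'
#' For each center, mean R and G channel intensities are taken over a disk of
#' radius `disk_frac` x spacing. An ommatidium is dark when its total
#' intensity R+G falls below `theta_dark` x the image-wide 95th percentile of
#' R+G; otherwise the redness index R/(R+G) decides: red when redness >=
#' `theta_red` (default 0.6), non-red otherwise. Centers outside the image
#' are skipped with a warning.
#'
#' @param centers data.frame from [detect_ommatidia()].
#' @param rgb an `rgb_image` from [map_to_rgb()].
#' @param spacing lattice spacing in pixels.
#' @param theta_dark,theta_red thresholds in (0, 1).
#' @param disk_frac averaging-disk radius as a fraction of the spacing.
#' @param reference absolute reference intensity replacing the internal
#'   95th percentile of R+G (used by [process_eyeshine_stack()] to anchor the
#'   dark threshold to the light-adapted frames, which keeps it meaningful
#'   even when the whole eyeshine image is dark).
#' @return data.frame with `row`, `col`, `mean_r`, `mean_g`, `redness`,
#'   `label` (factor red / non-red / dark).
#' @export
classify_ommatidia <- function(centers, rgb, spacing, theta_dark = 0.2,
                               theta_red = 0.6, disk_frac = 0.4,
                               reference = NULL) {
  stopifnot(inherits(rgb, "rgb_image"),
            theta_dark > 0, theta_dark < 1, theta_red > 0, theta_red < 1)
  nr <- nrow(rgb$R); nc <- ncol(rgb$R)
  inside <- centers$row >= 1 & centers$row <= nr &
            centers$col >= 1 & centers$col <= nc
  if (any(!inside)) {
    warning(sprintf("%d center(s) outside the image skipped", sum(!inside)))
    centers <- centers[inside, , drop = FALSE]
  }
  total <- rgb$R + rgb$G
  ref <- reference %||% stats::quantile(total, 0.95, names = FALSE)
  rad <- disk_frac * spacing
  res <- lapply(seq_len(nrow(centers)), function(i) {
    r0 <- centers$row[i]; c0 <- centers$col[i]
    rr <- max(1, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
    cc <- max(1, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    disk <- d2 <= rad^2
    mr <- mean(rgb$R[rr, cc][disk])
    mg <- mean(rgb$G[rr, cc][disk])
    redness <- if (mr + mg > 0) mr / (mr + mg) else NA_real_
    label <- if (mr + mg < theta_dark * ref) "dark"
             else if (redness >= theta_red) "red" else "non-red"
    data.frame(row = r0, col = c0, mean_r = mr, mean_g = mg,
               redness = redness, label = label)
  })
  out <- do.call(rbind, res)
  out$label <- factor(out$label, levels = c("red", "non-red", "dark"))
  out
}

#' Run the full eyeshine pipeline on one stack
#'
#' Background subtraction, RGB mapping, lattice detection and classification.
#' By default the lattice is detected on the pixelwise median of the
#' light-adapted background frames: every facet carries a corneal lens
#' reflection there, so dark ommatidia (which never appear in the eyeshine
#' itself) are still found as lattice positions - the role the upstream
#' lattice-detection step plays. With `detect_on = "eyeshine"` detection runs
#' on the cleaned eyeshine instead (pixelwise max of the R and G channels,
#' since red spots are absent from G), which cannot recover dark ommatidia.
#'
#' @param stack an [eyeshine_stack()].
#' @param spacing lattice spacing in pixels.
#' @param sigma background filter SD.
#' @param detect_on `"background"` (default) or `"eyeshine"`.
#' @param ... passed to [classify_ommatidia()].
#' @return the classification data.frame with `elevation` and `eye` columns.
#' @export
process_eyeshine_stack <- function(stack, spacing, sigma = 1,
                                   detect_on = c("background", "eyeshine"),
                                   ...) {
  detect_on <- match.arg(detect_on)
  cleaned <- subtract_background(stack, sigma)
  rgb <- map_to_rgb(cleaned)
  reference <- NULL
  det_img <- if (detect_on == "background") {
    mats <- stack$background_frames
    arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    med <- apply(arr, c(1, 2), stats::median)
    # the light-adapted frames carry a stable intensity scale (facet glints),
    # so anchor the dark threshold there; x2 because R+G sums two channels
    reference <- 2 * stats::quantile(med, 0.95, names = FALSE)
    med
  } else {
    pmax(rgb$R, rgb$G)
  }
  centers <- detect_ommatidia(det_img, spacing)
  if (nrow(centers) == 0) {
    return(cbind(data.frame(row = numeric(0), col = numeric(0),
                            mean_r = numeric(0), mean_g = numeric(0),
                            redness = numeric(0),
                            label = factor(character(0),
                                           levels = c("red", "non-red", "dark"))),
                 elevation = numeric(0), eye = character(0)))
  }
  det <- classify_ommatidia(centers, rgb, spacing, reference = reference, ...)
  det$elevation <- stack$elevation
  det$eye <- stack$eye
  det
}

#' Red / non-red / dark fraction profile along the dorso-ventral axis
#'
#' Fractions are computed per image (one elevation of one eye) so they sum to
#' exactly 1, then averaged (mean and SD) across replicate eyes per
#' elevation. Images with zero detections are excluded with a message.
#'
#' @param detections data.frame with columns `elevation`, `eye`, `label`
#'   (e.g. row-bound results of [process_eyeshine_stack()]).
#' @return list of class `fraction_profile` with `per_image` and
#'   `per_elevation` data.frames.
#' @export
fraction_profile <- function(detections) {
  stopifnot(all(c("elevation", "eye", "label") %in% names(detections)))
  key <- interaction(detections$elevation, detections$eye, drop = TRUE)
  per_image <- do.call(rbind, lapply(levels(key), function(k) {
    d <- detections[key == k, , drop = FALSE]
    n <- nrow(d)
    if (n == 0) return(NULL)
    f_red <- sum(d$label == "red") / n
    f_nonred <- sum(d$label == "non-red") / n
    # complement keeps the three fractions summing to exactly 1 in floating
    # point (n_red + n_nonred + n_dark == n holds by construction)
    data.frame(elevation = d$elevation[1], eye = d$eye[1], n = n,
               n_red = sum(d$label == "red"),
               n_nonred = sum(d$label == "non-red"),
               n_dark = sum(d$label == "dark"),
               f_red = f_red, f_nonred = f_nonred,
               f_dark = 1 - (f_red + f_nonred))
  }))
  if (is.null(per_image) || nrow(per_image) == 0) {
    stop("no images with detections")
  }
  agg <- function(v, e) c(mean = mean(v[per_image$elevation == e]),
                          sd = stats::sd(v[per_image$elevation == e]))
  elevs <- sort(unique(per_image$elevation))
  per_elevation <- do.call(rbind, lapply(elevs, function(e) {
    sel <- per_image$elevation == e
    data.frame(elevation = e, n_eyes = sum(sel),
               f_red = mean(per_image$f_red[sel]),
               sd_red = stats::sd(per_image$f_red[sel]),
               f_nonred = mean(per_image$f_nonred[sel]),
               sd_nonred = stats::sd(per_image$f_nonred[sel]),
               f_dark = mean(per_image$f_dark[sel]),
               sd_dark = stats::sd(per_image$f_dark[sel]))
  }))
  structure(list(per_image = per_image, per_elevation = per_elevation),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("<fraction_profile>\n")
  print(x$per_elevation, row.names = FALSE)
  invisible(x)
}
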
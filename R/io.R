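# CSV interfaces and end-to-end pipeline drivers (also used by the CLI in
# inst/cli/retinatune.R).

#' Read per-cell intensity runs from CSV
#'
#' Schema: `cell_id, od, response_mv, wavelength_nm`.
#'
#' @param path CSV file.
#' @return named list of [intensity_run()] objects, one per cell.
#' @export
read_intensity_runs <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$cell_id), function(di) {
    intensity_run(di$od, di$response_mv, di$wavelength_nm[1])
  })
}

#' Read spectral scans from CSV
#'
#' Schema: `cell_id, wavelength_nm, response_mv, sweep, adapt_wavelengths,
#' adapt_intensity`; `adapt_wavelengths` is empty for dark-adapted rows or a
#' `+`-separated list (e.g. `"550+450"`) for adapted rows.
#'
#' @param path CSV file.
#' @return nested list: per cell, a list of [spectral_scan()] objects named
#'   `dark` and `adapt_<wavelengths>`.
#' @export
read_spectral_scans <- function(path) {
  d <- utils::read.csv(path, colClasses = c(adapt_wavelengths = "character"))
  lapply(split(d, d$cell_id), function(di) {
    key <- ifelse(is.na(di$adapt_wavelengths) | di$adapt_wavelengths == "",
                  "dark", paste0("adapt_", di$adapt_wavelengths))
    out <- lapply(split(di, key), function(dk) {
      ad <- NULL
      if (dk$adapt_wavelengths[1] != "" && !is.na(dk$adapt_wavelengths[1])) {
        ad <- list(wavelengths = as.numeric(strsplit(dk$adapt_wavelengths[1],
                                                     "+", fixed = TRUE)[[1]]),
                   intensity = dk$adapt_intensity[1])
      }
      spectral_scan(dk$wavelength_nm, dk$response_mv, dk$sweep, adaptation = ad)
    })
    out
  })
}

#' Read polarization runs from CSV (`cell_id, angle_deg, response_mv`)
#'
#' @param path CSV file.
#' @return named list of [polarization_run()] objects.
#' @export
read_polarization_runs <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$cell_id), function(di) {
    polarization_run(di$angle_deg, di$response_mv)
  })
}

#' Run the electrophysiology pipeline over a scan directory
#'
#' Expects `intensity_run.csv` and `spectral_scan.csv` (optionally
#' `polarization_run.csv`) in `scans_dir`. Per cell: Hill fit, reverse-Hill
#' dark spectral sensitivity, optionally opponent-unit isolation from every
#' adapted scan, and polarization typing. Writes `sensitivity.csv`
#' (`cell_id, wavelength_nm, sensitivity, opponent_flag`) and, if
#' polarization data exist, `polarization.csv`.
#'
#' @param scans_dir input directory.
#' @param out_dir output directory (created if missing).
#' @param adapted also isolate opponent units from adapted scans.
#' @return invisibly, the sensitivity data.frame.
#' @export
run_ephys <- function(scans_dir, out_dir, adapted = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iruns <- read_intensity_runs(file.path(scans_dir, "intensity_run.csv"))
  scans <- read_spectral_scans(file.path(scans_dir, "spectral_scan.csv"))
  rows <- list()
  pol_rows <- list()
  pol_path <- file.path(scans_dir, "polarization_run.csv")
  pruns <- if (file.exists(pol_path)) read_polarization_runs(pol_path) else list()
  for (cid in names(scans)) {
    hp <- fit_hill(iruns[[cid]])
    dark <- suppressWarnings(reverse_hill(scans[[cid]]$dark, hp))
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = cid, wavelength_nm = dark$wavelength,
      sensitivity = dark$s, opponent_flag = FALSE)
    if (adapted) {
      for (nm in setdiff(names(scans[[cid]]), "dark")) {
        opp <- isolate_opponent_unit(dark, scans[[cid]][[nm]], hp)
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = paste0(cid, ":", nm), wavelength_nm = opp$wavelength,
          sensitivity = opp$s, opponent_flag = TRUE)
      }
    }
    if (cid %in% names(pruns)) {
      pr <- polarization_profile(pruns[[cid]], hp)
      pol_rows[[length(pol_rows) + 1]] <- data.frame(
        cell_id = cid, phi_max = pr$phi_max, ps = pr$ps,
        microvilli_class = pr$microvilli_class)
    }
  }
  sens <- do.call(rbind, rows)
  utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  if (length(pol_rows)) {
    utils::write.csv(do.call(rbind, pol_rows),
                     file.path(out_dir, "polarization.csv"), row.names = FALSE)
  }
  invisible(sens)
}

#' Run the two-template decomposition over a sensitivity table
#'
#' Reads a `sensitivity.csv` (as written by [run_ephys()], optionally with an
#' `elevation_deg` column), fits the 445+545 templates per cell in the
#' 400-600 nm window, classifies, flags UV-peaking cells, and - when
#' elevations are present - computes the dorso-ventral gradient profile.
#' Writes `cell_classes.csv` and `gradient_summary.json`.
#'
#' @param sens_file input CSV.
#' @param out_dir output directory.
#' @param bins elevation bin edges (degrees).
#' @param seed seed for the permutation test.
#' @return invisibly, the cell-classes data.frame.
#' @export
run_decompose <- function(sens_file, out_dir, bins = c(-90, -20, 10, 90),
                          seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- utils::read.csv(sens_file)
  has_elev <- "elevation_deg" %in% names(d)
  cells <- do.call(rbind, lapply(split(d, d$cell_id), function(di) {
    s <- spectral_sensitivity(di$wavelength_nm, di$sensitivity)
    fit <- fit_two_templates(s)
    uv <- if (min(di$wavelength_nm) <= 300 && max(di$wavelength_nm) >= 400) {
      detect_uv_peak(s)
    } else FALSE
    cell_record(di$cell_id[1],
                if (has_elev) di$elevation_deg[1] else NA_real_, fit, uv)
  }))
  utils::write.csv(data.frame(cell_id = cells$cell_id,
                              elevation_deg = cells$elevation,
                              a445 = cells$a445, a545 = cells$a545,
                              ratio = cells$ratio,
                              class_label = cells$class_label,
                              uv_peak = cells$uv_peak),
                   file.path(out_dir, "cell_classes.csv"), row.names = FALSE)
  if (has_elev && sum(!cells$uv_peak) >= 3) {
    gp <- gradient_profile(cells, bins = bins, seed = seed)
    jsonlite::write_json(
      list(bins = gp$bins, rho = gp$rho, p_perm = gp$p_perm, n = gp$n,
           seed = gp$seed),
      file.path(out_dir, "gradient_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(cells)
}

#' Run the mosaic pipeline over an ommatidium table
#'
#' Accepts either the raw intensity schema
#' (`id, x_um, y_um, r1_u, r1_b, r1_l, r2_u, r2_b, r2_l`) or the pre-called
#' schema (`id, x_um, y_um, r1_state, r2_state`). Writes `types.csv` and
#' `strip_profile.csv`.
#'
#' @param table_file input CSV.
#' @param out_dir output directory.
#' @param n_strips number of dorso-ventral strips.
#' @return invisibly, the [strip_densities()] profile.
#' @export
run_mosaic <- function(table_file, out_dir, n_strips = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- utils::read.csv(table_file)
  omm <- if ("r1_state" %in% names(tab)) {
    x <- tab[[if ("x" %in% names(tab)) "x" else "x_um"]]
    y <- tab[[if ("y" %in% names(tab)) "y" else "y_um"]]
    ommatidium_table(tab$id, x, y, tab$r1_state, tab$r2_state)
  } else {
    call_section_states(tab)
  }
  utils::write.csv(omm, file.path(out_dir, "types.csv"), row.names = FALSE)
  prof <- strip_densities(omm, n_strips)
  utils::write.csv(prof, file.path(out_dir, "strip_profile.csv"),
                   row.names = FALSE)
  invisible(prof)
}

#' Write an eyeshine stack as plain-text CSV frames
#'
#' One CSV matrix per frame, named `e<+EEE>_wl<WWW>.csv`, backgrounds with a
#' `_bg` suffix (text-only stand-in for TIFF/PNG stacks; see the vignette).
#'
#' @param stack an [eyeshine_stack()].
#' @param dir output directory.
#' @export
write_eyeshine_stack_csv <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in stack$wavelengths) {
    base <- sprintf("e%+04d_wl%03d", round(stack$elevation), w)
    utils::write.table(stack$frames[[as.character(w)]],
                       file.path(dir, paste0(base, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(stack$background_frames[[as.character(w)]],
                       file.path(dir, paste0(base, "_bg.csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read eyeshine stacks from a directory of CSV frames
#'
#' @param dir directory of `e<+EEE>_wl<WWW>[_bg].csv` frames (one elevation
#'   per `e` prefix).
#' @param eye replicate identifier attached to every stack.
#' @return list of [eyeshine_stack()] objects, one per elevation.
#' @export
read_eyeshine_stacks_csv <- function(dir, eye = "eye1") {
  files <- list.files(dir, pattern = "^e[+-][0-9]+_wl[0-9]+\\.csv$")
  if (!length(files)) stop("no eyeshine frames found in ", dir)
  info <- do.call(rbind, lapply(files, function(f) {
    m <- regmatches(f, regexec("^e([+-][0-9]+)_wl([0-9]+)\\.csv$", f))[[1]]
    data.frame(file = f, elevation = as.numeric(m[2]), wl = as.numeric(m[3]))
  }))
  lapply(split(info, info$elevation), function(gi) {
    frames <- list(); bgs <- list()
    for (i in seq_len(nrow(gi))) {
      fr <- as.matrix(utils::read.table(file.path(dir, gi$file[i]), sep = ","))
      bgf <- sub("\\.csv$", "_bg.csv", gi$file[i])
      bg <- as.matrix(utils::read.table(file.path(dir, bgf), sep = ","))
      dimnames(fr) <- dimnames(bg) <- NULL
      frames[[as.character(gi$wl[i])]] <- fr
      bgs[[as.character(gi$wl[i])]] <- bg
    }
    eyeshine_stack(frames, bgs, elevation = gi$elevation[1], eye = eye)
  })
}

#' Run the eyeshine pipeline over a directory of stacks
#'
#' Writes `detections.csv` (`elevation, eye, row, col, label, redness`) and
#' `fraction_profile.csv`.
#'
#' @param stacks_dir directory of CSV frames (see
#'   [read_eyeshine_stacks_csv()]).
#' @param out_dir output directory.
#' @param spacing lattice spacing in pixels.
#' @param eye replicate identifier.
#' @return invisibly, the [fraction_profile()].
#' @export
run_eyeshine <- function(stacks_dir, out_dir, spacing = 12, eye = "eye1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stacks <- read_eyeshine_stacks_csv(stacks_dir, eye = eye)
  det <- do.call(rbind, lapply(stacks, process_eyeshine_stack,
                               spacing = spacing))
  utils::write.csv(det[, c("elevation", "eye", "row", "col", "label", "redness")],
                   file.path(out_dir, "detections.csv"), row.names = FALSE)
  prof <- fraction_profile(det)
  utils::write.csv(prof$per_elevation,
                   file.path(out_dir, "fraction_profile.csv"), row.names = FALSE)
  invisible(prof)
}
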
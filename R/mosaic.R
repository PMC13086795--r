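# Ommatidial mosaic typing from immunolabel calls and strip-density profiles.

# Fixed canonical order of the five observed R1&2 expression states.
.CELL_STATES <- c("U", "B", "L", "UL", "BL")

#' Valid R1&2 expression states
#'
#' The five states observed in R1&2 cells: exclusive U, B or L opsin, or L
#' co-expressed with U (UL) or B (BL). U&B and U&B&L co-expression are never
#' observed and are rejected wherever states are constructed.
#'
#' @return character vector of the five states in canonical order
#'   U < B < L < UL < BL.
#' @export
cell_states <- function() .CELL_STATES

#' Call a cell's expression state from label intensities
#'
#' A channel is called positive when its intensity reaches its threshold.
#' The positive-channel set maps onto the five valid states; the forbidden
#' combinations (U&B with or without L) raise an invalid-state error and an
#' all-negative cell raises a no-call error.
#'
#' @param u,b,l label intensities (>= 0) for the UV, blue and long-wavelength
#'   opsin channels.
#' @param thresholds length-3 positive vector of per-channel thresholds
#'   (U, B, L order).
#' @return one of `"U"`, `"B"`, `"L"`, `"UL"`, `"BL"`.
#' @export
call_cell_state <- function(u, b, l, thresholds = c(1, 1, 1)) {
  stopifnot(length(thresholds) == 3, all(thresholds > 0),
            u >= 0, b >= 0, l >= 0)
  pos <- c(U = u >= thresholds[1], B = b >= thresholds[2], L = l >= thresholds[3])
  if (pos["U"] && pos["B"]) {
    stop("invalid-state error: U and B positive in the same cell")
  }
  if (!any(pos)) stop("no-call error: no channel reaches its threshold")
  if (pos["U"] && pos["L"]) "UL"
  else if (pos["B"] && pos["L"]) "BL"
  else names(pos)[pos]
}

#' Canonical unordered ommatidial type label
#'
#' Labels the R1&2 pair of an ommatidium order-independently using the fixed
#' state order U < B < L < UL < BL, e.g. `type_ommatidium("B", "U")` and
#' `type_ommatidium("U", "B")` both give `"U/B"`.
#'
#' @param s1,s2 states from [cell_states()].
#' @return character label `"<first>/<second>"`.
#' @export
type_ommatidium <- function(s1, s2) {
  i1 <- match(s1, .CELL_STATES)
  i2 <- match(s2, .CELL_STATES)
  if (any(is.na(c(i1, i2)))) stop("invalid cell state")
  paste(.CELL_STATES[sort(c(i1, i2))], collapse = "/")
}

#' Enumerate the ommatidial type space
#'
#' All unordered pairs (with repetition) of the given states: k states yield
#' k(k+1)/2 types. The full five-state space {U, B, L, UL, BL} yields the 15
#' observed ommatidial types.
#'
#' @param states distinct states from [cell_states()]; default all five.
#' @return character vector of canonical type labels.
#' @export
enumerate_type_space <- function(states = cell_states()) {
  if (length(states) == 0) stop("states must be non-empty")
  if (anyDuplicated(states)) stop("states must be distinct")
  states <- .CELL_STATES[sort(match(states, .CELL_STATES))]
  if (any(is.na(states))) stop("invalid cell state")
  out <- character(0)
  for (i in seq_along(states)) {
    for (j in i:length(states)) {
      out <- c(out, paste(states[i], states[j], sep = "/"))
    }
  }
  out
}

#' Categorize an ommatidial type for strip-density profiling
#'
#' Collapses the 15 types into the four panel categories: `nonL` (both R1&2
#' in {U, B}: non-red ommatidia), `L` (L expressed but no co-expression),
#' `UL` (any UL cell) and `BL` (any BL cell, no UL). The single mixed UL/BL
#' type goes to `UL` (UL is the rarer class; configurable).
#'
#' @param type_label a label from [type_ommatidium()].
#' @param ul_bl_category category receiving the mixed UL/BL type, `"UL"`
#'   (default) or `"BL"`.
#' @return one of `"nonL"`, `"L"`, `"UL"`, `"BL"`.
#' @export
categorize_ommatidium <- function(type_label, ul_bl_category = c("UL", "BL")) {
  ul_bl_category <- match.arg(ul_bl_category)
  parts <- strsplit(type_label, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || any(!parts %in% .CELL_STATES)) {
    stop("invalid type label: ", type_label)
  }
  has_ul <- "UL" %in% parts
  has_bl <- "BL" %in% parts
  if (has_ul && has_bl) ul_bl_category
  else if (has_ul) "UL"
  else if (has_bl) "BL"
  else if (all(parts %in% c("U", "B"))) "nonL"
  else "L"
}

#' Assemble an ommatidium table from per-cell states
#'
#' @param id identifiers.
#' @param x,y section coordinates (micrometres or pixels); larger `y` =
#'   more dorsal.
#' @param r1_state,r2_state states from [cell_states()].
#' @return data.frame with added `type_label` and `category` columns.
#' @export
ommatidium_table <- function(id, x, y, r1_state, r2_state) {
  n <- length(id)
  stopifnot(length(x) == n, length(y) == n,
            length(r1_state) == n, length(r2_state) == n)
  type_label <- mapply(type_ommatidium, r1_state, r2_state, USE.NAMES = FALSE)
  category <- vapply(type_label, categorize_ommatidium, character(1),
                     USE.NAMES = FALSE)
  data.frame(id = id, x = x, y = y, r1_state = r1_state, r2_state = r2_state,
             type_label = type_label, category = category)
}

#' Strip-density profile along the dorso-ventral axis
#'
#' Divides the section into `n_strips` horizontal strips of equal width
#' spanning the bounding box along the dorso-ventral (y) axis, counts the
#' four categories per strip and normalizes to the per-strip total, so that
#' per strip N = n_nonL + n_L + n_UL + n_BL and the four fractions sum to 1.
#' Strip 1 is the dorsal-most strip (largest y). Empty strips report NA
#' fractions, not zero.
#'
#' @param section a data.frame from [ommatidium_table()] (needs `y` and
#'   `category`).
#' @param n_strips number of strips (default 10).
#' @return data.frame of class `strip_profile`: strip, N, the four counts and
#'   the four fractions.
#' @export
strip_densities <- function(section, n_strips = 10) {
  stopifnot(nrow(section) >= 1, all(c("y", "category") %in% names(section)))
  yr <- range(section$y)
  if (diff(yr) <= 0) stop("bounding box degenerate along the dorso-ventral axis")
  edges <- seq(yr[1], yr[2], length.out = n_strips + 1)
  idx <- findInterval(section$y, edges, rightmost.closed = TRUE)
  strip <- n_strips + 1L - idx  # strip 1 = dorsal-most (largest y)
  cats <- c("nonL", "L", "UL", "BL")
  out <- do.call(rbind, lapply(seq_len(n_strips), function(k) {
    cc <- section$category[strip == k]
    n <- length(cc)
    counts <- vapply(cats, function(ct) sum(cc == ct), integer(1))
    fr <- if (n > 0) counts / n else rep(NA_real_, 4)
    data.frame(strip = k, N = n,
               n_nonL = counts[1], n_L = counts[2], n_UL = counts[3], n_BL = counts[4],
               f_nonL = fr[1], f_L = fr[2], f_UL = fr[3], f_BL = fr[4])
  }))
  rownames(out) <- NULL
  structure(out, class = c("strip_profile", "data.frame"))
}

#' Call all cell states of an intensity table
#'
#' Applies [call_cell_state()] to a raw intensity table with per-channel
#' thresholds; when thresholds are missing they default to an Otsu threshold
#' computed per channel over both R1&2 cells (the upstream protocol
#' classifies by eye; Otsu keeps the automated pipeline unsupervised).
#'
#' @param tab data.frame with columns `id`, `x`, `y` (or `x_um`, `y_um`) and
#'   `r1_u`, `r1_b`, `r1_l`, `r2_u`, `r2_b`, `r2_l`.
#' @param thresholds optional length-3 vector (U, B, L).
#' @return an [ommatidium_table()].
#' @export
call_section_states <- function(tab, thresholds = NULL) {
  nm <- names(tab)
  x <- tab[[if ("x" %in% nm) "x" else "x_um"]]
  y <- tab[[if ("y" %in% nm) "y" else "y_um"]]
  need <- c("r1_u", "r1_b", "r1_l", "r2_u", "r2_b", "r2_l")
  stopifnot(all(need %in% nm))
  if (is.null(thresholds)) {
    thresholds <- c(otsu_threshold(c(tab$r1_u, tab$r2_u)),
                    otsu_threshold(c(tab$r1_b, tab$r2_b)),
                    otsu_threshold(c(tab$r1_l, tab$r2_l)))
  }
  # U&B double positives are never biologically observed: when noise pushes
  # both channels over threshold, keep the stronger one and report it
  n_conflict <- 0L
  call_one <- function(u, b, l) {
    if (u >= thresholds[1] && b >= thresholds[2]) {
      n_conflict <<- n_conflict + 1L
      if (u / thresholds[1] >= b / thresholds[2]) b <- 0 else u <- 0
    }
    call_cell_state(u, b, l, thresholds)
  }
  r1 <- mapply(call_one, tab$r1_u, tab$r1_b, tab$r1_l)
  r2 <- mapply(call_one, tab$r2_u, tab$r2_b, tab$r2_l)
  if (n_conflict > 0) {
    message(sprintf("resolved %d U/B double-positive cell(s) toward the stronger channel",
                    n_conflict))
  }
  ommatidium_table(tab$id, x, y, r1, r2)
}
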
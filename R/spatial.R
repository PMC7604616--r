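# Per-cell spatial statistics on mask rasters and point patterns:
# Peripheral Distribution Index (PDI), peripheral/perinuclear intensity
# ratios, PLA dot calling and compartment assignment.
#
# Masks are logical matrices indexed [row, col]; a point (x, y) has
# x = column and y = row, with pixel centers at integer coordinates.
# Analysis is 2D (maximum-intensity-projection convention).

#' Construct a cell geometry from cell and nucleus masks
#'
#' @param cell_mask,nucleus_mask logical (or 0/1) matrices of equal size;
#'   the nucleus must be contained in the cell and both must be non-empty
#'   and connected.
#' @param pixel_size physical pixel size (micron/px), default 1.
#' @return A `cell_geometry` object with the masks, centroids (x, y) and the
#'   cell's equivalent radius `sqrt(area / pi)`.
#' @export
cell_geometry <- function(cell_mask, nucleus_mask, pixel_size = 1) {
  cell_mask <- matrix(as.logical(cell_mask), nrow = nrow(cell_mask))
  nucleus_mask <- matrix(as.logical(nucleus_mask), nrow = nrow(nucleus_mask))
  if (!identical(dim(cell_mask), dim(nucleus_mask)))
    stop("cell and nucleus masks must have identical dimensions",
         call. = FALSE)
  if (!any(cell_mask) || !any(nucleus_mask))
    stop("cell and nucleus masks must be non-empty", call. = FALSE)
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus mask is not contained in the cell mask", call. = FALSE)
  for (m in list(cell = cell_mask, nucleus = nucleus_mask)) {
    if (max(EBImage::bwlabel(m)) > 1)
      stop("mask is not connected", call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size, "pixel_size", 0, strict = TRUE)
  centroid <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  }
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 pixel_size = pixel_size,
                 cell_centroid = centroid(cell_mask),
                 nucleus_centroid = centroid(nucleus_mask),
                 equiv_radius = sqrt(sum(cell_mask) / pi)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell_geometry: %d x %d px, cell area %d px^2, nucleus area %d px^2\n",
              nrow(x$cell_mask), ncol(x$cell_mask),
              sum(x$cell_mask), sum(x$nucleus_mask)))
  invisible(x)
}

# squared distance of each TRUE pixel of `mask` from point (x, y)
mask_sq_distances <- function(mask, point) {
  idx <- which(mask, arr.ind = TRUE)
  (idx[, 2] - point["x"])^2 + (idx[, 1] - point["y"])^2
}

#' Construct a spot set
#'
#' Spots falling outside the cell mask are dropped with a warning; the number
#' dropped is recorded in attribute `n_dropped`.
#'
#' @param x,y spot coordinates (x = column, y = row, px).
#' @param intensity optional per-spot intensity.
#' @param cell a [cell_geometry()] used to validate membership (optional).
#' @return A `spot_set` data frame.
#' @export
spot_set <- function(x, y, intensity = NULL, cell = NULL) {
  stopifnot(length(x) == length(y))
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  n_dropped <- 0L
  if (!is.null(cell) && nrow(df)) {
    inside <- points_in_mask(df$x, df$y, cell$cell_mask)
    n_dropped <- sum(!inside)
    if (n_dropped > 0) {
      warning(sprintf("%d spot(s) outside the cell mask were dropped",
                      n_dropped), call. = FALSE)
      df <- df[inside, , drop = FALSE]
    }
  }
  structure(df, class = c("spot_set", "data.frame"), n_dropped = n_dropped)
}

points_in_mask <- function(x, y, mask) {
  r <- round(y); c <- round(x)
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  ok[ok] <- mask[cbind(r[ok], c[ok])]
  ok
}

#' Peripheral Distribution Index of a spot pattern
#'
#' PDI is the second moment of the spots about the nucleus centroid divided
#' by the second moment of the cell mask about the same point:
#' \deqn{PDI = \mathrm{mean}_i\, d_i^2 \; / \; \mathrm{mean}_p\, d_p^2}
#' with d the Euclidean distance from the nucleus centroid, i over spots and
#' p over cell pixels. PDI = 0 when all spots sit at the nucleus centroid,
#' approximately 1 for a diffuse (uniform) pattern, > 1 for peripheral and
#' < 1 for perinuclear patterns. The ratio is invariant to isotropic
#' rescaling and translation of the whole scene.
#'
#' @param cell a [cell_geometry()].
#' @param spots a [spot_set()] or data frame with `x`, `y`.
#' @return A list with `pdi`, `n_spots` and `reference_moment` (px^2).
#' @export
compute_pdi <- function(cell, spots) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (!is.data.frame(spots) || nrow(spots) == 0)
    stop("at least one spot is required to compute a PDI", call. = FALSE)
  ref <- mean(mask_sq_distances(cell$cell_mask, cell$nucleus_centroid))
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate cell mask: zero reference moment", call. = FALSE)
  d2 <- (spots$x - cell$nucleus_centroid["x"])^2 +
    (spots$y - cell$nucleus_centroid["y"])^2
  list(pdi = unname(mean(d2) / ref), n_spots = nrow(spots),
       reference_moment = unname(ref))
}

#' Peripheral / perinuclear compartment specification
#'
#' Band widths are in px; when `NULL` they default to `band_frac` times the
#' cell's equivalent radius (10% by default).
#'
#' @param peripheral_width width of the band inward from the cell edge (px).
#' @param perinuclear_width width of the band outward from the nucleus edge
#'   (px).
#' @param band_frac fraction of the equivalent radius used when a width is
#'   `NULL`.
#' @export
compartment_spec <- function(peripheral_width = NULL,
                             perinuclear_width = NULL,
                             band_frac = 0.1) {
  if (!is.null(peripheral_width))
    stop_if_not_scalar_number(peripheral_width, "peripheral_width", 0, TRUE)
  if (!is.null(perinuclear_width))
    stop_if_not_scalar_number(perinuclear_width, "perinuclear_width", 0, TRUE)
  stop_if_not_scalar_number(band_frac, "band_frac", 0, TRUE)
  structure(list(peripheral_width = peripheral_width,
                 perinuclear_width = perinuclear_width,
                 band_frac = band_frac),
            class = "compartment_spec")
}

resolve_band_widths <- function(cell, spec) {
  w <- spec$band_frac * cell$equiv_radius
  list(wp = if (is.null(spec$peripheral_width)) w else spec$peripheral_width,
       wn = if (is.null(spec$perinuclear_width)) w else spec$perinuclear_width)
}

#' Peripheral and perinuclear band masks of a cell
#'
#' The peripheral band is the set of cell pixels within `peripheral_width`
#' of the cell boundary (distance to the nearest outside pixel); the
#' perinuclear band is the set of cell pixels outside the nucleus within
#' `perinuclear_width` of the nucleus boundary.
#'
#' @inheritParams compute_pdi
#' @param spec a [compartment_spec()].
#' @return A list of two logical masks, `peripheral` and `perinuclear`.
#' @export
compartment_bands <- function(cell, spec = compartment_spec()) {
  stopifnot(inherits(cell, "cell_geometry"))
  w <- resolve_band_widths(cell, spec)
  d_edge <- EBImage::distmap(EBImage::Image(cell$cell_mask * 1))
  peripheral <- cell$cell_mask & as.matrix(d_edge) <= w$wp
  d_nuc <- EBImage::distmap(EBImage::Image((1 - cell$nucleus_mask) * 1))
  perinuclear <- cell$cell_mask & !cell$nucleus_mask &
    as.matrix(d_nuc) <= w$wn
  if (!any(peripheral) || !any(perinuclear))
    stop("empty compartment band for this geometry", call. = FALSE)
  if (any(peripheral & perinuclear))
    stop("peripheral and perinuclear bands overlap; reduce band widths",
         call. = FALSE)
  list(peripheral = peripheral, perinuclear = perinuclear)
}

#' Peripheral / perinuclear intensity ratio
#'
#' Mean image intensity over the peripheral band divided by the mean over
#' the perinuclear band. A zero perinuclear mean yields `ratio = Inf` with
#' `flag = "zero_perinuclear_mean"` rather than an error.
#'
#' @inheritParams compartment_bands
#' @param image numeric matrix of intensities, same size as the masks.
#' @return A list with `ratio`, `peripheral_mean`, `perinuclear_mean`,
#'   `flag` (`NA` when clean).
#' @export
peripheral_perinuclear_ratio <- function(cell, image,
                                         spec = compartment_spec()) {
  stopifnot(is.matrix(image), identical(dim(image), dim(cell$cell_mask)))
  bands <- compartment_bands(cell, spec)
  pm <- mean(image[bands$peripheral])
  nm <- mean(image[bands$perinuclear])
  if (nm == 0) {
    list(ratio = Inf, peripheral_mean = pm, perinuclear_mean = nm,
         flag = "zero_perinuclear_mean")
  } else {
    list(ratio = pm / nm, peripheral_mean = pm, perinuclear_mean = nm,
         flag = NA_character_)
  }
}

#' PLA dot-calling parameters
#'
#' Background is estimated robustly over the cell mask (median, and SD as
#' MAD x 1.4826, insensitive to the dots themselves); a pixel is candidate
#' signal when strictly brighter than `median + k_sd * SD` (default 3 SD,
#' matching threshold-based PLA dot counting).
#'
#' @param k_sd threshold multiplier (> 0).
#' @param min_dot_area minimum connected-component area in px^2 (>= 1).
#' @export
pla_params <- function(k_sd = 3, min_dot_area = 4) {
  stop_if_not_scalar_number(k_sd, "k_sd", 0, strict = TRUE)
  stop_if_not_scalar_number(min_dot_area, "min_dot_area", 1)
  structure(list(k_sd = k_sd, min_dot_area = min_dot_area),
            class = "pla_params")
}

#' Call PLA dots in an intensity image
#'
#' Pixels inside the cell strictly above the robust background threshold are
#' grouped into connected components; components of at least `min_dot_area`
#' pixels become dots, located at their intensity-weighted centroid.
#'
#' @param image numeric intensity matrix covering the cell mask.
#' @inheritParams compute_pdi
#' @param params a [pla_params()].
#' @return A data frame of dots (`x`, `y`, `peak`, `area`) with attributes
#'   `background_median`, `background_sd`, `threshold`.
#' @export
call_pla_dots <- function(image, cell, params = pla_params()) {
  stopifnot(is.matrix(image), identical(dim(image), dim(cell$cell_mask)))
  vals <- image[cell$cell_mask]
  bg <- stats::median(vals)
  bg_sd <- stats::mad(vals)  # MAD x 1.4826
  if (bg_sd == 0)
    stop("flat image: background SD is zero", call. = FALSE)
  thr <- bg + params$k_sd * bg_sd
  cand <- cell$cell_mask & image > thr  # strict inequality
  empty <- data.frame(x = numeric(), y = numeric(), peak = numeric(),
                      area = integer())
  out <- empty
  if (any(cand)) {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(cand * 1)))
    comps <- split(which(cand), lab[cand])
    rows <- lapply(comps, function(px) {
      if (length(px) < params$min_dot_area) return(NULL)
      rr <- (px - 1) %% nrow(image) + 1
      cc <- (px - 1) %/% nrow(image) + 1
      w <- image[px]
      data.frame(x = sum(cc * w) / sum(w), y = sum(rr * w) / sum(w),
                 peak = max(w), area = length(px))
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out <- out[order(out$x, out$y), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, background_median = bg, background_sd = bg_sd,
            threshold = thr)
}

#' Assign called dots to peripheral band or cell body
#'
#' A dot is peripheral when its center lies in the peripheral band,
#' otherwise it belongs to the cell body; totals are conserved. Dots whose
#' centers fall outside the cell mask are excluded with a warning and
#' reported in `n_excluded`.
#'
#' @inheritParams compartment_bands
#' @param dots data frame with `x`, `y` columns (e.g. from
#'   [call_pla_dots()]).
#' @return A list with `n_total`, `n_peripheral`, `n_body`, `n_excluded`.
#' @export
classify_dots <- function(cell, dots, spec = compartment_spec()) {
  stopifnot(is.data.frame(dots))
  bands <- compartment_bands(cell, spec)
  if (nrow(dots) == 0)
    return(list(n_total = 0L, n_peripheral = 0L, n_body = 0L,
                n_excluded = 0L))
  inside <- points_in_mask(dots$x, dots$y, cell$cell_mask)
  n_excluded <- sum(!inside)
  if (n_excluded > 0)
    warning(sprintf("%d dot(s) outside the cell mask were excluded",
                    n_excluded), call. = FALSE)
  dots <- dots[inside, , drop = FALSE]
  peri <- points_in_mask(dots$x, dots$y, bands$peripheral)
  list(n_total = nrow(dots), n_peripheral = as.integer(sum(peri)),
       n_body = as.integer(sum(!peri)), n_excluded = as.integer(n_excluded))
}
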
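#' Stain-detection configuration
#'
#' @param k_mad detection threshold in MADs above the sheet median.
#' @param diameter_range_mm accepted equivalent-diameter range for a
#'   connected component to count as one stain, mm. Under noise the
#'   thresholded component of a high-%HbS stain is its center spot only
#'   (about 5 mm) while low-%HbS stains threshold at their full extent, so
#'   the range must span both.
#' @param bin_width_mm radial-profile bin width used for geometry, mm.
#' @param geometry a [geometry_config()] (its `background`, when `NULL`, is
#'   filled with the sheet median at detection time).
#' @param c_radius_mm,half_width_mm C-index sampling annulus geometry, mm.
#' @return A `detection_config` list.
#' @export
detection_config <- function(k_mad = 5, diameter_range_mm = c(4, 25),
                             bin_width_mm = 0.2,
                             geometry = geometry_config(),
                             c_radius_mm = 5.0, half_width_mm = 0.25) {
  stopifnot(k_mad > 0, length(diameter_range_mm) == 2,
            diameter_range_mm[1] < diameter_range_mm[2])
  structure(list(k_mad = k_mad, diameter_range_mm = diameter_range_mm,
                 bin_width_mm = bin_width_mm, geometry = geometry,
                 c_radius_mm = c_radius_mm, half_width_mm = half_width_mm),
            class = "detection_config")
}

# Crop a window of +/- radius_mm around a sub-pixel center; returns the
# cropped intensity_map and the center's coordinates within the crop.
crop_around <- function(map, center_xy, radius_mm) {
  H <- nrow(map$values); W <- ncol(map$values)
  half <- ceiling(mm_to_px(radius_mm, map$dpi))
  cols <- max(1L, floor(center_xy[1]) - half):min(W, floor(center_xy[1]) + half)
  rows <- max(1L, floor(center_xy[2]) - half):min(H, floor(center_xy[2]) + half)
  list(map = intensity_map(map$values[rows, cols, drop = FALSE], map$dpi,
                           map$source_id),
       center = c(center_xy[1] - cols[1] + 1, center_xy[2] - rows[1] + 1))
}

#' Detect stains in a scanned sheet
#'
#' The sheet background level is estimated as the median intensity; pixels
#' more than `k_mad` MADs above it are thresholded and connected components
#' whose equivalent diameter falls inside the configured range are retained
#' as stains. Each stain's center is the intensity-weighted centroid of its
#' component (weights are intensities in excess of the median), and its
#' radii come from [estimate_geometry()] on the radial profile around that
#' center. Components touching the image border are discarded; components
#' wider than 1.5 times the maximum accepted diameter are reported on the
#' warnings channel as possible merged stains. Results are ordered row-major
#' (top row of stains first, left to right).
#'
#' @param sheet an [intensity_map()] of the whole sheet.
#' @param config a [detection_config()].
#' @return A data frame with one row per detected stain (`stain_id`,
#'   `center_x`, `center_y`, `r_center_mm`, `r_outer_mm`,
#'   `eq_diameter_mm`); possible-merge messages in `attr(, "warnings")`.
#'   Zero rows when nothing qualifies.
#' @export
detect_stains <- function(sheet, config = detection_config()) {
  stopifnot(inherits(sheet, "intensity_map"))
  v <- sheet$values
  H <- nrow(v); W <- ncol(v)
  med <- stats::median(v)
  madv <- stats::mad(v)
  thr <- med + config$k_mad * madv
  mask <- v > thr
  warnings <- character(0)
  empty <- data.frame(stain_id = character(0), center_x = numeric(0),
                      center_y = numeric(0), r_center_mm = numeric(0),
                      r_outer_mm = numeric(0), eq_diameter_mm = numeric(0))
  if (!any(mask)) return(structure(empty, warnings = warnings))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), H, W)
  n_comp <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = n_comp)
  eq_d <- px_to_mm(2 * sqrt(areas / pi), sheet$dpi)
  rows_idx <- row(v); cols_idx <- col(v)
  keep <- logical(n_comp)
  out <- vector("list", n_comp)
  for (k in seq_len(n_comp)) {
    if (eq_d[k] > 1.5 * config$diameter_range_mm[2]) {
      warnings <- c(warnings, sprintf(
        "component %d spans %.1f mm, more than 1.5x the maximum stain diameter: possible merged stains",
        k, eq_d[k]))
    }
    if (eq_d[k] < config$diameter_range_mm[1] ||
        eq_d[k] > config$diameter_range_mm[2]) next
    sel <- lab == k
    rr <- rows_idx[sel]; cc <- cols_idx[sel]
    if (min(rr) == 1L || max(rr) == H || min(cc) == 1L || max(cc) == W) next
    w <- pmax(v[sel] - med, 0)
    if (sum(w) == 0) w <- rep(1, length(w))
    center <- c(sum(w * cc) / sum(w), sum(w * rr) / sum(w))
    cropped <- crop_around(sheet, center, config$diameter_range_mm[2] / 2 + 1)
    prof <- compute_radial_profile(cropped$map, cropped$center,
                                   bin_width_mm = config$bin_width_mm,
                                   max_radius_mm = config$diameter_range_mm[2] / 2)
    gcfg <- config$geometry
    if (is.null(gcfg$background)) gcfg$background <- med
    geom <- estimate_geometry(prof, gcfg)
    keep[k] <- TRUE
    out[[k]] <- data.frame(center_x = center[1], center_y = center[2],
                           r_center_mm = geom$r_center,
                           r_outer_mm = geom$r_outer,
                           eq_diameter_mm = eq_d[k])
  }
  if (!any(keep)) return(structure(empty, warnings = warnings))
  res <- do.call(rbind, out[keep])
  # row-major ordering: cluster centers into rows, then sort left to right
  ord <- order(res$center_y)
  res <- res[ord, ]
  gap <- mm_to_px(config$diameter_range_mm[1] / 2, sheet$dpi)
  band <- cumsum(c(1, diff(res$center_y) > gap))
  res <- res[order(band, res$center_x), ]
  res <- cbind(stain_id = sprintf("det%02d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  structure(res, warnings = warnings)
}

#' Detect and score every stain in an image
#'
#' Runs the full per-sheet analysis: intensity conversion (if given an RGB
#' [stain_image()]), detection, geometry, then S-index and C-index per
#' stain. Stains whose 5 mm C-index annulus falls outside the image get
#' `NA` for the C-index with a warning rather than failing the sheet.
#'
#' @param image a [stain_image()] or [intensity_map()].
#' @param config a [detection_config()].
#' @return Data frame with columns `source_id`, `stain_id`, `center_x_px`,
#'   `center_y_px`, `r_center_mm`, `r_outer_mm`, `s_index`, `c_index`;
#'   detection warnings carried in `attr(, "warnings")`.
#' @export
analyze_image <- function(image, config = detection_config()) {
  map <- if (inherits(image, "stain_image")) to_intensity(image) else image
  stopifnot(inherits(map, "intensity_map"))
  det <- detect_stains(map, config)
  warns <- attr(det, "warnings")
  n <- nrow(det)
  res <- data.frame(source_id = rep(map$source_id, n),
                    stain_id = det$stain_id,
                    center_x_px = det$center_x, center_y_px = det$center_y,
                    r_center_mm = det$r_center_mm,
                    r_outer_mm = det$r_outer_mm,
                    s_index = rep(NA_real_, n), c_index = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  crop_mm <- max(config$diameter_range_mm[2] / 2,
                 config$c_radius_mm + config$half_width_mm) + 1
  for (i in seq_len(n)) {
    cr <- crop_around(map, c(det$center_x[i], det$center_y[i]), crop_mm)
    res$s_index[i] <- compute_s_index(cr$map, cr$center,
                                      det$r_center_mm[i], det$r_outer_mm[i])
    res$c_index[i] <- tryCatch(
      compute_c_index(cr$map, cr$center, det$r_center_mm[i],
                      c_radius_mm = config$c_radius_mm,
                      half_width_mm = config$half_width_mm),
      error = function(e) {
        warns <<- c(warns, sprintf("%s: C-index not computed (%s)",
                                   det$stain_id[i], conditionMessage(e)))
        NA_real_
      })
  }
  structure(res, warnings = warns)
}

#' Write per-stain results as CSV
#'
#' @param results data frame from [analyze_image()] (possibly with call
#'   columns appended by the classifiers).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stain_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
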
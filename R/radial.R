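#' Radial intensity profile around a stain center
#'
#' Pixels are grouped by their pixel-center distance to the (sub-pixel)
#' stain center, converted to millimetres via the DPI, and averaged in
#' annular bins of constant width. Empty bins are omitted.
#'
#' @param stain an [intensity_map()].
#' @param center_xy stain center, `c(x, y)` in pixel coordinates
#'   (x = column, y = row).
#' @param bin_width_mm radial bin width, mm.
#' @param max_radius_mm profile cut-off; defaults to the largest radius that
#'   fits in the image.
#' @return A data frame of class `radial_profile` with columns
#'   `bin_center_mm`, `mean_intensity` and `n_px`.
#' @export
compute_radial_profile <- function(stain, center_xy, bin_width_mm = 0.2,
                                   max_radius_mm = NULL) {
  stopifnot(inherits(stain, "intensity_map"), bin_width_mm > 0)
  H <- nrow(stain$values); W <- ncol(stain$values)
  if (center_xy[1] < 1 || center_xy[1] > W || center_xy[2] < 1 || center_xy[2] > H)
    stop("center lies outside the image", call. = FALSE)
  r <- pixel_radii_mm(H, W, center_xy, stain$dpi)
  if (is.null(max_radius_mm)) max_radius_mm <- max(r)
  keep <- r <= max_radius_mm
  bin <- floor(r[keep] / bin_width_mm)
  sums <- tapply(stain$values[keep], bin, sum)
  cnts <- tapply(rep(1, sum(keep)), bin, sum)
  idx <- as.integer(names(sums))
  prof <- data.frame(bin_center_mm = (idx + 0.5) * bin_width_mm,
                     mean_intensity = as.numeric(sums / cnts),
                     n_px = as.integer(cnts))
  prof <- prof[order(prof$bin_center_mm), ]
  rownames(prof) <- NULL
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

#' Geometry-estimation configuration
#'
#' @param fraction_center the center-spot boundary is the first radius where
#'   the profile falls below `background + fraction_center * (plateau -
#'   background)`, with the plateau taken as the mean of bins within
#'   `plateau_mm` of the center.
#' @param fraction_outer the outer radius is the last radius at which the
#'   profile still exceeds `background + fraction_outer * (ring_level -
#'   background)`, where `ring_level` is the profile maximum beyond the
#'   provisional center-spot boundary. Referencing the ring rather than the
#'   (much brighter) center peak keeps the dim peripheral ring of
#'   high-%HbS stains inside the detected extent.
#' @param outer_min_excess absolute floor (intensity units) on the
#'   outer threshold's excess over background, guarding against noise and
#'   against stains with essentially no ring.
#' @param plateau_mm radius defining the central plateau, mm.
#' @param background baseline intensity; `NULL` estimates it from the
#'   outermost 10% of profile bins.
#' @param min_r_center_mm lower clamp for the center-spot radius, mm.
#' @param margin_mm clamp gap kept between `r_center` and `r_outer`, mm.
#' @return A `geometry_config` list.
#' @export
geometry_config <- function(fraction_center = 0.5, fraction_outer = 0.1,
                            outer_min_excess = 1.0,
                            plateau_mm = 1.0, background = NULL,
                            min_r_center_mm = 0.5, margin_mm = 0.5) {
  stopifnot(fraction_center > 0, fraction_center < 1,
            fraction_outer > 0, fraction_outer < 1, outer_min_excess >= 0)
  structure(list(fraction_center = fraction_center,
                 fraction_outer = fraction_outer,
                 outer_min_excess = outer_min_excess,
                 plateau_mm = plateau_mm,
                 background = background, min_r_center_mm = min_r_center_mm,
                 margin_mm = margin_mm),
            class = "geometry_config")
}

#' Estimate center-spot and outer radii from a radial profile
#'
#' The center-spot radius is where the profile first drops below
#' `fraction_center` of the central plateau's excess over background; the
#' outer radius is where it finally decays below `fraction_outer` of the
#' ring level's excess (with an absolute floor of `outer_min_excess`
#' intensity units). When the profile never drops below the center
#' threshold before the outer edge (very flat stains), `r_center` is
#' clamped to `r_outer - margin_mm`.
#'
#' @param profile a [compute_radial_profile()] result with at least 5 bins.
#' @param config a [geometry_config()].
#' @return A list of class `stain_geometry` with `r_center`, `r_outer` (mm)
#'   and the background used.
#' @export
estimate_geometry <- function(profile, config = geometry_config()) {
  stopifnot(inherits(profile, "radial_profile"))
  if (nrow(profile) < 5) stop("profile needs at least 5 bins", call. = FALSE)
  r <- profile$bin_center_mm
  v <- profile$mean_intensity
  bg <- config$background
  if (is.null(bg)) {
    tail_n <- max(3L, ceiling(0.1 * length(v)))
    bg <- mean(utils::tail(v, tail_n))
  }
  peak <- max(v)
  if (peak - bg <= .Machine$double.eps * 255)
    stop("profile is entirely at background: no stain", call. = FALSE)
  plateau <- mean(v[r <= max(config$plateau_mm, r[1])])
  thr_cen <- bg + config$fraction_center * (plateau - bg)
  # ring level: profile maximum past the provisional center boundary plus a
  # 1 mm buffer that skips the smoothed disk-edge falloff
  prov <- which(v < thr_cen)
  ring_level <- peak
  if (length(prov)) {
    r_prov <- r[min(prov)]
    beyond <- r > r_prov + 1.0
    if (!any(beyond)) beyond <- r > r_prov
    if (any(beyond)) ring_level <- max(v[beyond])
  }
  thr_out <- bg + max(config$outer_min_excess,
                      config$fraction_outer * (ring_level - bg))
  above <- which(v >= thr_out)
  if (!length(above))
    stop("profile is entirely at background: no stain", call. = FALSE)
  r_outer <- r[max(above)]
  below <- which(v < thr_cen & r <= r_outer)
  r_center <- if (length(below)) r[min(below)] else r_outer - config$margin_mm
  r_center <- min(max(r_center, config$min_r_center_mm),
                  r_outer - config$margin_mm)
  structure(list(r_center = r_center, r_outer = r_outer, background = bg),
            class = "stain_geometry")
}
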
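#' S-index: center-to-ring mean intensity ratio
#'
#' The S-index is the quotient of the mean red color intensity of pixels in
#' the center spot (pixel-center distance at most `r_center`) and the mean
#' intensity of pixels in the half-open peripheral ring (distance in
#' `(r_center, r_outer]`, so every pixel belongs to exactly one region).
#' The center spot collects polymerized HbS, the ring the soluble
#' hemoglobins, so the ratio tracks the HbS fraction of total hemoglobin and
#' is insensitive to overall stain brightness. Raw intensities are used by
#' default (no background subtraction); the optional flag subtracts a
#' supplied baseline from both means before dividing.
#'
#' @param stain an [intensity_map()] of one stain.
#' @param center_xy stain center `c(x, y)`, pixels.
#' @param r_center_mm,r_outer_mm region radii, mm.
#' @param background_subtract subtract `background` from both region means.
#' @param background baseline intensity used when subtracting.
#' @return The S-index (unitless, non-negative).
#' @export
compute_s_index <- function(stain, center_xy, r_center_mm, r_outer_mm,
                            background_subtract = FALSE, background = 0) {
  stopifnot(inherits(stain, "intensity_map"), r_center_mm > 0,
            r_center_mm < r_outer_mm)
  r <- pixel_radii_mm(nrow(stain$values), ncol(stain$values), center_xy,
                      stain$dpi)
  in_center <- r <= r_center_mm
  in_ring <- r > r_center_mm & r <= r_outer_mm
  if (!any(in_ring)) stop("ring region contains no pixels", call. = FALSE)
  m_c <- mean(stain$values[in_center])
  m_r <- mean(stain$values[in_ring])
  if (background_subtract) {
    m_c <- m_c - background
    m_r <- m_r - background
  }
  if (m_r == 0)
    stop(structure(class = c("stainscore_undefined_index", "error", "condition"),
                   list(message = "ring mean intensity is zero: S-index undefined",
                        call = NULL)))
  m_c / m_r
}

#' C-index: total center intensity times mean intensity at 5 mm
#'
#' The C-index is the product of the summed red color intensity of all
#' center-spot pixels and the mean intensity of pixels at a fixed distance
#' (default 5 mm) from the stain center. Unlike the S-index it scales with
#' the absolute amount of hemoglobin deposited, which lets it separate HbSC
#' samples (typically anemic) from HbAS carriers with similar %HbS. The
#' "circle at 5 mm" is realized as a thin annulus of half-width
#' `half_width_mm` so that it contains pixel centers.
#'
#' @inheritParams compute_s_index
#' @param c_radius_mm radius of the sampling circle, mm.
#' @param half_width_mm half-width of the sampling annulus, mm.
#' @return The C-index (non-negative; intensity-squared units).
#' @export
compute_c_index <- function(stain, center_xy, r_center_mm,
                            c_radius_mm = 5.0, half_width_mm = 0.25) {
  stopifnot(inherits(stain, "intensity_map"), r_center_mm > 0,
            c_radius_mm > 0, half_width_mm > 0)
  H <- nrow(stain$values); W <- ncol(stain$values)
  reach_px <- mm_to_px(c_radius_mm + half_width_mm, stain$dpi)
  if (center_xy[1] - reach_px < 1 || center_xy[1] + reach_px > W ||
      center_xy[2] - reach_px < 1 || center_xy[2] + reach_px > H)
    stop("5 mm sampling annulus extends outside the image", call. = FALSE)
  r <- pixel_radii_mm(H, W, center_xy, stain$dpi)
  in_center <- r <= r_center_mm
  in_annulus <- abs(r - c_radius_mm) <= half_width_mm
  if (!any(in_annulus)) stop("sampling annulus contains no pixels", call. = FALSE)
  sum(stain$values[in_center]) * mean(stain$values[in_annulus])
}
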
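#' Parameters of the synthetic stain generator
#'
#' The generator renders the characteristic two-compartment pattern the
#' solubility assay produces on chromatography paper: deoxygenated HbS
#' polymerizes, is retained at the deposition point and forms a dark red
#' center spot, while soluble hemoglobins (HbA, HbF, HbC) wick outward and
#' form a lighter peripheral ring. Red color intensity (255 - Blue) follows a
#' radial two-compartment model: a disk of radius `r_center_mm` carrying the
#' HbS mass share and an annulus out to `r_outer_mm` carrying the soluble
#' share, with edge smoothing and optional pixel noise.
#'
#' Mass partitioning uses two leak terms: a fraction `leak_center` of the
#' soluble hemoglobin is retained in the center (incomplete wicking), and a
#' fraction `leak_ring` of the HbS escapes into the ring (incomplete
#' polymer trapping). With `p = percent_hbs/100` the center carries
#' `(1 - leak_ring) * p + leak_center * (1 - p)` of the deposited mass and
#' the ring the complement, so total deposited mass is conserved exactly.
#'
#' Deposited mass scales as `hb_conc * droplet_volume / (1 + dilution)`: the
#' droplet is a blood:buffer mixture at ratio `1:dilution`, so only
#' `1/(1 + dilution)` of its volume is blood. The stain radius scales with
#' the square root of droplet volume times total dilution factor relative to
#' the 20 uL, 1:10 reference (two-dimensional spreading of the liquid).
#'
#' @param percent_hbs fraction of total hemoglobin that is HbS, in percent
#'   (0--100).
#' @param hb_conc total hemoglobin concentration of the blood sample, g/dL.
#' @param dilution blood:buffer volume ratio denominator; 10 means 1:10.
#' @param droplet_volume volume of the deposited mixture droplet, uL.
#' @param dpi resolution of the rendered raster, dots per inch.
#' @param r_center_mm nominal center-spot radius at the reference metering,
#'   mm.
#' @param r_outer_mm nominal outer stain radius at the reference metering,
#'   mm.
#' @param leak_center fraction of soluble Hb retained in the center spot.
#' @param leak_ring fraction of HbS escaping into the ring.
#' @param background baseline intensity of blank paper, 0--255.
#' @param noise_sd additive Gaussian pixel noise SD, intensity units.
#' @param edge_sigma_mm Gaussian edge-smoothing scale, mm.
#' @param gain rendering gain: intensity times mm^2 per unit of deposited
#'   hemoglobin mass (g/dL x uL). Calibrated so in-band stains sit well above
#'   the detection threshold without saturating.
#' @param seed integer seed for the stain's pseudo-random stream.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(percent_hbs = 0, hb_conc = 14, dilution = 10,
                             droplet_volume = 20, dpi = 300,
                             r_center_mm = 2.5, r_outer_mm = 7.5,
                             leak_center = 0.15, leak_ring = 0.05,
                             background = 10, noise_sd = 3,
                             edge_sigma_mm = 0.2, gain = 180, seed = 1L) {
  p <- structure(list(percent_hbs = percent_hbs, hb_conc = hb_conc,
                      dilution = dilution, droplet_volume = droplet_volume,
                      dpi = dpi, r_center_mm = r_center_mm,
                      r_outer_mm = r_outer_mm, leak_center = leak_center,
                      leak_ring = leak_ring, background = background,
                      noise_sd = noise_sd, edge_sigma_mm = edge_sigma_mm,
                      gain = gain, seed = as.integer(seed)),
                 class = "generator_params")
  validate_generator_params(p)
  p
}

#' @rdname generator_params
#' @param params a `generator_params` object to validate.
#' @export
validate_generator_params <- function(params) {
  with(params, {
    if (percent_hbs < 0 || percent_hbs > 100)
      stop("percent_hbs must lie in [0, 100]", call. = FALSE)
    if (hb_conc <= 0) stop("hb_conc must be positive", call. = FALSE)
    if (dilution <= 0) stop("dilution must be positive", call. = FALSE)
    if (droplet_volume <= 0) stop("droplet_volume must be positive", call. = FALSE)
    if (leak_center < 0 || leak_center >= 1 || leak_ring < 0 || leak_ring >= 1)
      stop("leak terms must lie in [0, 1)", call. = FALSE)
    if (r_center_mm <= 0 || r_center_mm >= r_outer_mm)
      stop("need 0 < r_center_mm < r_outer_mm", call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
    if (background < 0) stop("background must be non-negative", call. = FALSE)
    if (dpi <= 0) stop("dpi must be positive", call. = FALSE)
  })
  invisible(params)
}

# Metering scale: stain radii relative to the 20 uL, 1:10 reference,
# assuming spread area proportional to droplet volume x dilution factor.
stain_scale <- function(params) {
  sqrt((params$droplet_volume / 20) * ((1 + params$dilution) / 11))
}

# Deposited hemoglobin mass in g/dL x uL units (proportional to true mass).
stain_mass <- function(params) {
  params$hb_conc * params$droplet_volume / (1 + params$dilution)
}

# Closed-form radial model pieces. Edges are smoothed on the radial
# coordinate with a Gaussian of scale sigma (erf profile), the shape a
# Gaussian blur imprints on a sharp-edged radially symmetric stain.
disk_shape <- function(r, r_c, sigma) stats::pnorm((r_c - r) / sigma)
ring_shape <- function(r, r_c, r_o, sigma)
  stats::pnorm((r - r_c) / sigma) * stats::pnorm((r_o - r) / sigma)

#' Evaluate the noise-free radial intensity model
#'
#' Closed-form expectation of the rendered intensity at radius `r_mm` from
#' the stain center, before noise and clipping. Exposed so tests and users
#' can integrate the model independently of the raster rendering.
#'
#' @param r_mm radius (vector), mm.
#' @param params a [generator_params()].
#' @return Intensity values on the 0--255 scale (not clipped).
#' @export
stain_model <- function(r_mm, params) {
  a <- stain_amplitudes(params)
  params$background +
    a$A_center * disk_shape(r_mm, a$r_c, a$sigma) +
    a$A_ring * ring_shape(r_mm, a$r_c, a$r_o, a$sigma)
}

# Amplitudes normalized by the continuous integral of each smoothed shape,
# so that integral(intensity - background) dA = gain * mass exactly.
stain_amplitudes <- function(params) {
  sc <- stain_scale(params)
  r_c <- params$r_center_mm * sc
  r_o <- params$r_outer_mm * sc
  sigma <- params$edge_sigma_mm
  p <- params$percent_hbs / 100
  share_center <- (1 - params$leak_ring) * p + params$leak_center * (1 - p)
  share_ring <- 1 - share_center
  upper <- r_o + 10 * sigma
  I_disk <- stats::integrate(function(r) disk_shape(r, r_c, sigma) * 2 * pi * r,
                             0, upper, rel.tol = 1e-10)$value
  I_ring <- stats::integrate(function(r) ring_shape(r, r_c, r_o, sigma) * 2 * pi * r,
                             0, upper, rel.tol = 1e-10)$value
  m <- stain_mass(params) * params$gain
  list(A_center = share_center * m / I_disk,
       A_ring = share_ring * m / I_ring,
       r_c = r_c, r_o = r_o, sigma = sigma)
}

# Radii (mm) of every pixel center from a sub-pixel center (x = col, y = row).
pixel_radii_mm <- function(nrow, ncol, center_xy, dpi) {
  dx <- px_to_mm(seq_len(ncol) - center_xy[1], dpi)
  dy <- px_to_mm(seq_len(nrow) - center_xy[2], dpi)
  sqrt(outer(dy^2, dx^2, `+`))
}

# Render intensity into RGB: only Blue carries signal (B = 255 - I);
# Red saturated, Green at half depth for a realistic pink-to-dark-red look.
render_rgb <- function(intensity, dpi, source_id) {
  px <- array(0, dim = c(nrow(intensity), ncol(intensity), 3L))
  px[, , 1] <- 255
  px[, , 2] <- pmax(0, pmin(255, 255 - 0.5 * intensity))
  px[, , 3] <- pmax(0, pmin(255, 255 - intensity))
  stain_image(px, dpi = dpi, source_id = source_id)
}

check_saturation <- function(model_vals, radii, r_stain) {
  in_stain <- radii <= r_stain
  frac <- mean(model_vals[in_stain] >= 255)
  if (frac > 0.01)
    stop(structure(class = c("stainscore_saturation_error", "error", "condition"),
                   list(message = sprintf(
                     "amplitude saturates %.1f%% of stain pixels at 255; reduce gain, hb_conc or droplet concentration (saturation breaks index linearity)",
                     100 * frac), call = NULL)))
  invisible(frac)
}

#' Generate one synthetic stain with known ground truth
#'
#' Renders the radial two-compartment model on a pixel grid, applies
#' additive Gaussian noise, clips to `[0, 255]` and packs the result as an
#' RGB [stain_image()]. Deterministic given `params$seed`.
#'
#' @param params a [generator_params()].
#' @param genotype_label optional genotype the parameters were drawn for
#'   (`"AA"`, `"AS"`, `"SS"`, `"SC"`, `"SBplus"`); recorded in the truth.
#' @param stain_id identifier recorded in the truth.
#' @return A list with elements `image` (a [stain_image()]) and `truth`
#'   (one-row data frame: stain_id, genotype, percent_hbs, hb_conc,
#'   center_x_px, center_y_px, seed).
#' @export
generate_stain <- function(params, genotype_label = NA_character_,
                           stain_id = "stain1") {
  validate_generator_params(params)
  a <- stain_amplitudes(params)
  half_mm <- max(a$r_o + 3 * a$sigma, 5.5) + 2
  half_px <- ceiling(mm_to_px(half_mm, params$dpi))
  n <- 2L * half_px + 1L
  center <- c(half_px + 1, half_px + 1)  # exact pixel center
  radii <- pixel_radii_mm(n, n, center, params$dpi)
  model <- stain_model(radii, params)
  check_saturation(model, radii, a$r_o + 3 * a$sigma)
  intens <- if (params$noise_sd > 0) {
    with_seed(params$seed,
              model + stats::rnorm(length(model), sd = params$noise_sd))
  } else model
  intens <- matrix(pmax(0, pmin(255, intens)), n, n)
  img <- render_rgb(intens, params$dpi,
                    sprintf("synthetic:%s", stain_id))
  truth <- data.frame(stain_id = stain_id, genotype = genotype_label,
                      percent_hbs = params$percent_hbs,
                      hb_conc = params$hb_conc,
                      center_x_px = center[1], center_y_px = center[2],
                      seed = params$seed, stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Sheet layout for arrays of stains
#'
#' @param nrow,ncol grid dimensions.
#' @param pitch_mm center-to-center spacing of grid cells, mm.
#' @param margin_mm blank margin around the grid, mm.
#' @param jitter_mm maximum center placement jitter (uniform, each axis), mm.
#' @return A `sheet_layout` list.
#' @export
sheet_layout <- function(nrow = 2, ncol = 4, pitch_mm = 25, margin_mm = 12,
                         jitter_mm = 0.5) {
  stopifnot(nrow >= 1, ncol >= 1, pitch_mm > 0, margin_mm >= 0, jitter_mm >= 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pitch_mm = pitch_mm, margin_mm = margin_mm,
                 jitter_mm = jitter_mm),
            class = "sheet_layout")
}

#' Generate a sheet carrying an array of stains
#'
#' Places one stain per grid cell (row-major) with small random center
#' jitter, composites the noise-free models additively on a common
#' background, then applies one sheet-wide noise pass. All samples must share
#' dpi, background and noise_sd (one physical sheet, one scan).
#'
#' @param samples list of [generator_params()], at most `nrow * ncol`.
#' @param layout a [sheet_layout()].
#' @param seed integer governing jitter and sheet noise.
#' @param labels optional genotype labels, recycled into the truth table.
#' @param ids optional stain identifiers (default `"s01"`, `"s02"`, ...).
#' @return A list with `image` (a [stain_image()] of the whole sheet) and
#'   `truth` (data frame, one row per stain).
#' @export
generate_sheet <- function(samples, layout = sheet_layout(), seed = 1L,
                           labels = NULL, ids = NULL) {
  stopifnot(inherits(layout, "sheet_layout"))
  n <- length(samples)
  if (n > layout$nrow * layout$ncol)
    stop("layout grid too small for ", n, " samples", call. = FALSE)
  if (n > 0) {
    for (p in samples) validate_generator_params(p)
    dpi <- samples[[1]]$dpi
    bg <- samples[[1]]$background
    nsd <- samples[[1]]$noise_sd
    same <- vapply(samples, function(p)
      p$dpi == dpi && p$background == bg && p$noise_sd == nsd, logical(1))
    if (!all(same))
      stop("all samples on a sheet must share dpi, background and noise_sd",
           call. = FALSE)
    amps <- lapply(samples, stain_amplitudes)
    ext <- vapply(amps, function(a) a$r_o + 3 * a$sigma, numeric(1))
    if (any(2 * ext + 2 * layout$jitter_mm > layout$pitch_mm))
      stop("stain outer diameters overlap at this pitch (layout error)",
           call. = FALSE)
  } else {
    dpi <- 300; bg <- 10; nsd <- 0
  }
  W_mm <- 2 * layout$margin_mm + layout$ncol * layout$pitch_mm
  H_mm <- 2 * layout$margin_mm + layout$nrow * layout$pitch_mm
  W <- ceiling(mm_to_px(W_mm, dpi)); H <- ceiling(mm_to_px(H_mm, dpi))
  canvas <- matrix(bg, H, W)
  truth <- data.frame(stain_id = character(0), genotype = character(0),
                      percent_hbs = numeric(0), hb_conc = numeric(0),
                      center_x_px = numeric(0), center_y_px = numeric(0),
                      seed = integer(0), stringsAsFactors = FALSE)
  if (is.null(ids) && n > 0) ids <- sprintf("s%02d", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- rep_len(labels, max(n, 0L))
  canvas <- with_seed(seed, {
    if (n > 0) {
      jit <- matrix(stats::runif(2 * n, -layout$jitter_mm, layout$jitter_mm),
                    ncol = 2)
      for (i in seq_len(n)) {
        row <- (i - 1L) %/% layout$ncol + 1L
        col <- (i - 1L) %% layout$ncol + 1L
        cx_mm <- layout$margin_mm + (col - 0.5) * layout$pitch_mm + jit[i, 1]
        cy_mm <- layout$margin_mm + (row - 0.5) * layout$pitch_mm + jit[i, 2]
        cx <- mm_to_px(cx_mm, dpi); cy <- mm_to_px(cy_mm, dpi)
        a <- amps[[i]]
        half_px <- ceiling(mm_to_px(a$r_o + 3 * a$sigma + 1, dpi))
        cols <- max(1L, floor(cx) - half_px):min(W, floor(cx) + half_px)
        rows <- max(1L, floor(cy) - half_px):min(H, floor(cy) + half_px)
        dx <- px_to_mm(cols - cx, dpi); dy <- px_to_mm(rows - cy, dpi)
        radii <- sqrt(outer(dy^2, dx^2, `+`))
        model <- stain_model(radii, samples[[i]])
        check_saturation(model, radii, a$r_o + 3 * a$sigma)
        canvas[rows, cols] <- canvas[rows, cols] + (model - bg)
        truth[i, ] <- list(ids[i], labels[i], samples[[i]]$percent_hbs,
                           samples[[i]]$hb_conc, cx, cy, samples[[i]]$seed)
      }
    }
    if (nsd > 0) canvas <- canvas + stats::rnorm(length(canvas), sd = nsd)
    canvas
  })
  canvas <- matrix(pmax(0, pmin(255, canvas)), H, W)
  list(image = render_rgb(canvas, dpi, sprintf("synthetic-sheet:seed%d", seed)),
       truth = truth)
}

#' Cohort composition and genotype bands
#'
#' Per-genotype subject counts plus the %HbS bands and total-Hb ranges the
#' generator draws from. Default counts mirror a 55-subject screening cohort
#' (18 HbAA, 17 HbAS, 20 HbSS). Bands: carriers (AS) 38--42 %HbS, HbSC
#' 41--50, HbSS 74--93, S-beta+-thalassemia above 60; HbSS and HbSC subjects
#' are drawn anemic (lower total Hb) as in clinical populations.
#'
#' @param n_aa,n_as,n_ss,n_sc,n_sbplus subject counts per genotype.
#' @param percent_bands named list of `c(lo, hi)` %HbS bands.
#' @param hb_ranges named list of `c(lo, hi)` total-Hb ranges, g/dL.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_aa = 18, n_as = 17, n_ss = 20, n_sc = 0,
                        n_sbplus = 0,
                        percent_bands = list(AA = c(0, 0), AS = c(38, 42),
                                             SS = c(74, 93), SC = c(41, 50),
                                             SBplus = c(60, 93)),
                        hb_ranges = list(AA = c(12, 16.5), AS = c(12, 16.5),
                                         SS = c(6.2, 11), SC = c(8, 11),
                                         SBplus = c(7, 12))) {
  counts <- c(AA = n_aa, AS = n_as, SS = n_ss, SC = n_sc, SBplus = n_sbplus)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, percent_bands = percent_bands,
                 hb_ranges = hb_ranges),
            class = "cohort_spec")
}

#' Draw a synthetic cohort of stains with known genotypes
#'
#' For each subject, %HbS is drawn uniformly in the genotype's band and
#' total Hb uniformly in the genotype's range; a per-stain seed is derived
#' from the cohort seed. Deterministic given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer cohort seed.
#' @param base_params a [generator_params()] supplying all non-subject
#'   parameters (dpi, radii, leaks, noise, ...).
#' @param render if `TRUE`, render one [stain_image()] per subject; set
#'   `FALSE` to get parameters and truth only (e.g. before sheet placement).
#' @return A list with `params` (list of [generator_params()]), `truth`
#'   (data frame) and `stains` (list of images, or `NULL`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            base_params = generator_params(),
                            render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- spec$counts[spec$counts > 0]
  n <- sum(counts)
  draws <- with_seed(seed, {
    out <- list()
    subseeds <- sample.int(2147483646L, max(n, 1L))
    k <- 0L
    for (g in names(counts)) {
      band <- spec$percent_bands[[g]]
      hbr <- spec$hb_ranges[[g]]
      for (i in seq_len(counts[[g]])) {
        k <- k + 1L
        out[[k]] <- list(genotype = g,
                         percent_hbs = stats::runif(1, band[1], band[2]),
                         hb_conc = stats::runif(1, hbr[1], hbr[2]),
                         seed = subseeds[k])
      }
    }
    out
  })
  params <- lapply(draws, function(d) {
    p <- base_params
    p$percent_hbs <- d$percent_hbs
    p$hb_conc <- d$hb_conc
    p$seed <- d$seed
    validate_generator_params(p)
    p
  })
  ids <- sprintf("s%03d", seq_along(draws))
  labels <- vapply(draws, `[[`, character(1), "genotype")
  stains <- NULL
  truth <- data.frame(stain_id = ids, genotype = labels,
                      percent_hbs = vapply(draws, `[[`, numeric(1), "percent_hbs"),
                      hb_conc = vapply(draws, `[[`, numeric(1), "hb_conc"),
                      center_x_px = rep(NA_real_, length(draws)),
                      center_y_px = rep(NA_real_, length(draws)),
                      seed = vapply(draws, function(d) as.integer(d$seed), integer(1)),
                      stringsAsFactors = FALSE)
  if (render && length(params) > 0) {
    rendered <- Map(generate_stain, params, labels, ids)
    stains <- lapply(rendered, `[[`, "image")
    centers <- t(vapply(rendered, function(r)
      c(r$truth$center_x_px, r$truth$center_y_px), numeric(2)))
    truth$center_x_px <- centers[, 1]
    truth$center_y_px <- centers[, 2]
  }
  list(params = params, truth = truth, stains = stains)
}

#' Percent HbS of volume mixtures of an HbSS sample with HbAA blood
#'
#' When an HbSS sample is diluted with HbAA blood matched for total Hb,
#' %HbS of the mixture is linear in the HbSS volume fraction.
#'
#' @param percent_hbs_ss %HbS of the undiluted HbSS sample (0--100).
#' @param fractions HbSS volume fractions in `[0, 1]`.
#' @return `fractions * percent_hbs_ss`.
#' @export
mix_dilution_series <- function(percent_hbs_ss, fractions) {
  if (percent_hbs_ss < 0 || percent_hbs_ss > 100)
    stop("percent_hbs_ss must lie in [0, 100]", call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  fractions * percent_hbs_ss
}

#' Simulate dilution-series calibration data
#'
#' Emulates a calibration experiment in which HbSS samples of high known
#' %HbS are volume-mixed with matched HbAA blood at 11 fractions (10:0 down
#' to 0:10) and the S-index of each mixture is measured. Measured %HbS is
#' the linear response `slope * s_index` plus Gaussian error.
#'
#' @param n_source number of HbSS source samples (default 4, giving
#'   `4 x 11 = 44` points per series).
#' @param fractions mixing fractions (default 10:0 ... 0:10 in steps of 0.1).
#' @param slope true %HbS per unit S-index.
#' @param noise_sd Gaussian error SD on measured %HbS.
#' @param ss_range range the source samples' %HbS is drawn from.
#' @param seed integer seed.
#' @return Data frame with columns `s_index` and `percent_hbs`.
#' @export
simulate_calibration_series <- function(n_source = 4,
                                        fractions = seq(1, 0, by = -0.1),
                                        slope = 12.1, noise_sd = 6.4,
                                        ss_range = c(74, 93), seed = 1L) {
  with_seed(seed, {
    src <- stats::runif(n_source, ss_range[1], ss_range[2])
    true_pct <- unlist(lapply(src, mix_dilution_series, fractions = fractions))
    s <- true_pct / slope
    data.frame(s_index = s,
               percent_hbs = true_pct + stats::rnorm(length(s), sd = noise_sd))
  })
}

#' Write / read a ground-truth table as CSV
#'
#' Columns: stain_id, genotype, percent_hbs, hb_conc, center_x_px,
#' center_y_px, seed.
#'
#' @param truth ground-truth data frame as returned by the generators.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
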
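# Shared fixtures: everything is generated in code at test time.

# Render one stain and score it with the analysis chain (truth center).
index_stain <- function(params, geometry = geometry_config(background = params$background)) {
  st <- generate_stain(params)
  m <- to_intensity(st$image)
  ctr <- c(st$truth$center_x_px, st$truth$center_y_px)
  prof <- compute_radial_profile(m, ctr, bin_width_mm = 0.2, max_radius_mm = 10)
  g <- estimate_geometry(prof, geometry)
  list(map = m, center = ctr, geom = g,
       s = compute_s_index(m, ctr, g$r_center, g$r_outer),
       c = compute_c_index(m, ctr, g$r_center))
}

# S-index over a cohort using truth centers (no detection), for speed.
cohort_s_indices <- function(spec, seed, base_params) {
  co <- generate_cohort(spec, seed = seed, base_params = base_params)
  s <- vapply(seq_along(co$stains), function(i) {
    m <- to_intensity(co$stains[[i]])
    ctr <- c(co$truth$center_x_px[i], co$truth$center_y_px[i])
    prof <- compute_radial_profile(m, ctr, 0.2, max_radius_mm = 10)
    g <- estimate_geometry(prof, geometry_config(background = base_params$background))
    compute_s_index(m, ctr, g$r_center, g$r_outer)
  }, numeric(1))
  list(s = s, truth = co$truth)
}

# Full simulate -> detect -> score round trip over sheets of 8.
roundtrip_cohort <- function(spec = cohort_spec(), seed = 42,
                             base_params = generator_params(noise_sd = 0)) {
  co <- generate_cohort(spec, seed = seed, base_params = base_params,
                        render = FALSE)
  n <- length(co$params)
  layout <- sheet_layout(nrow = 2, ncol = 4, pitch_mm = 22, margin_mm = 10)
  res <- list(); truth <- list()
  for (sh in seq_len(ceiling(n / 8))) {
    idx <- ((sh - 1) * 8 + 1):min(sh * 8, n)
    sheet <- generate_sheet(co$params[idx], layout, seed = seed + sh,
                            labels = co$truth$genotype[idx],
                            ids = co$truth$stain_id[idx])
    sheet$truth$sheet <- sprintf("sheet%d", sh)
    r <- analyze_image(sheet$image)
    r$source_id <- sprintf("sheet%d", sh)
    res[[sh]] <- r
    truth[[sh]] <- sheet$truth
  }
  match_detections(do.call(rbind, res), do.call(rbind, truth))
}

# Independent Mann-Whitney AUC: pairwise comparisons, ties counted 1/2.
mann_whitney_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
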
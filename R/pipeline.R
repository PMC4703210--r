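#' Run configuration
#'
#' One plain-text-serializable object carrying every tunable of a full run:
#' scan resolution, detection and geometry parameters, classification
#' cutoffs (or a path to a pinned model config), CI convention and seed.
#'
#' @param dpi scan resolution.
#' @param detection a [detection_config()].
#' @param thresholds a [thresholds()] object or `NULL` (fit from data).
#' @param ci_convention `"standard"` or `"cohort_total"`.
#' @param seed integer seed for simulation subcommands.
#' @return A `run_config` list.
#' @export
run_config <- function(dpi = 300, detection = detection_config(),
                       thresholds = NULL,
                       ci_convention = c("standard", "cohort_total"),
                       seed = 1L) {
  ci_convention <- match.arg(ci_convention)
  structure(list(dpi = dpi, detection = detection, thresholds = thresholds,
                 ci_convention = ci_convention, seed = as.integer(seed)),
            class = "run_config")
}

# Config hash for provenance blocks: md5 of the deparsed config.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

provenance_block <- function(config, seed) {
  c(sprintf("package: stainscore %s",
            as.character(utils::packageVersion("stainscore"))),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("seed: %d", seed),
    sprintf("date: %s", format(Sys.Date())))
}

#' Simulate a cohort of stain sheets on disk
#'
#' Draws a cohort, lays the stains out on as many sheets as the layout
#' requires, and writes sheet PNGs plus a ground-truth CSV (with per-sheet
#' pixel centers) into `out_dir`.
#'
#' @param out_dir writable output directory (created if absent).
#' @param spec a [cohort_spec()].
#' @param layout a [sheet_layout()] used for every sheet.
#' @param config a [run_config()]; its seed governs all draws.
#' @param base_params generator defaults for non-subject parameters.
#' @return Invisibly, a list with `sheets` (PNG paths) and `truth_csv`.
#' @export
run_simulate <- function(out_dir, spec = cohort_spec(),
                         layout = sheet_layout(nrow = 2, ncol = 4),
                         config = run_config(),
                         base_params = generator_params(dpi = config$dpi)) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  cohort <- generate_cohort(spec, seed = config$seed,
                            base_params = base_params, render = FALSE)
  n <- length(cohort$params)
  per_sheet <- layout$nrow * layout$ncol
  n_sheets <- if (n == 0) 0L else ceiling(n / per_sheet)
  paths <- character(0)
  truth_all <- list()
  for (sh in seq_len(n_sheets)) {
    idx <- ((sh - 1L) * per_sheet + 1L):min(sh * per_sheet, n)
    ids <- cohort$truth$stain_id[idx]
    sheet <- generate_sheet(cohort$params[idx], layout,
                            seed = config$seed + sh,
                            labels = cohort$truth$genotype[idx], ids = ids)
    p <- file.path(out_dir, sprintf("sheet%02d.png", sh))
    write_stain_image(sheet$image, p)
    sheet$truth$sheet <- basename(p)
    paths <- c(paths, p)
    truth_all[[sh]] <- sheet$truth
  }
  truth <- if (n_sheets > 0) do.call(rbind, truth_all) else
    cbind(cohort$truth, sheet = character(0))
  truth_csv <- file.path(out_dir, "ground_truth.csv")
  write_ground_truth(truth, truth_csv)
  writeLines(provenance_block(config, config$seed),
             file.path(out_dir, "provenance.txt"))
  invisible(list(sheets = paths, truth_csv = truth_csv, truth = truth))
}

#' Analyze one or more scanned sheets
#'
#' Reads each image, runs detection and index computation, optionally
#' appends genotype calls when thresholds are configured, and writes one
#' per-stain CSV. Detection warnings are emitted via `message()`, never
#' fatal.
#'
#' @param images character vector of image paths, or a list of
#'   [stain_image()] objects.
#' @param config a [run_config()] (supplies dpi, detection parameters and
#'   optional thresholds).
#' @param out_csv optional path for the per-stain result CSV.
#' @return The per-stain results data frame. Zero rows when no stain is
#'   found in any image.
#' @export
run_analyze <- function(images, config = run_config(), out_csv = NULL) {
  imgs <- if (is.character(images)) {
    lapply(images, read_stain_image, dpi = config$dpi)
  } else images
  res <- list()
  for (img in imgs) {
    r <- analyze_image(img, config$detection)
    for (w in attr(r, "warnings")) message("warning: ", w)
    res[[length(res) + 1L]] <- r
  }
  res <- do.call(rbind, res)
  if (!is.null(config$thresholds) && nrow(res) > 0) {
    res$call <- classify_s_index(res$s_index, config$thresholds)
    if (is.finite(config$thresholds$c_cutoff)) {
      res$extended_call <- ifelse(
        res$call == "AS" & is.finite(res$c_index),
        classify_c_index(res$c_index, config$thresholds$c_cutoff),
        NA_character_)
    }
  }
  if (!is.null(out_csv)) write_stain_results(res, out_csv)
  res
}

#' Match detected stains to ground truth by center proximity
#'
#' Greedy nearest-center matching between a detection/result table and a
#' generator truth table; useful for validating the analyzer against the
#' synthetic generator where detection order need not follow truth order.
#'
#' @param results data frame with `center_x_px`, `center_y_px` (per sheet
#'   `source_id` when present).
#' @param truth ground-truth data frame with `center_x_px`, `center_y_px`
#'   and optionally `sheet`.
#' @param max_dist_px matches farther than this are dropped.
#' @return `results` with truth columns (`truth_id`, `genotype`,
#'   `percent_hbs`, `hb_conc`) and `center_error_px` appended; unmatched
#'   rows are removed.
#' @export
match_detections <- function(results, truth, max_dist_px = 25) {
  match_one <- function(res, tru) {
    if (nrow(res) == 0 || nrow(tru) == 0) return(NULL)
    d <- outer(res$center_x_px, tru$center_x_px, `-`)^2 +
      outer(res$center_y_px, tru$center_y_px, `-`)^2
    d <- sqrt(d)
    out <- list()
    while (any(is.finite(d)) && min(d) <= max_dist_px) {
      ij <- arrayInd(which.min(d), dim(d))
      i <- ij[1]; j <- ij[2]
      row <- res[i, , drop = FALSE]
      row$truth_id <- tru$stain_id[j]
      row$genotype <- tru$genotype[j]
      row$percent_hbs <- tru$percent_hbs[j]
      row$hb_conc <- tru$hb_conc[j]
      row$center_error_px <- d[i, j]
      out[[length(out) + 1L]] <- row
      d[i, ] <- Inf; d[, j] <- Inf
    }
    do.call(rbind, out)
  }
  if ("sheet" %in% names(truth) && "source_id" %in% names(results)) {
    sheets <- unique(truth$sheet)
    matched <- lapply(sheets, function(s)
      match_one(results[results$source_id == s, , drop = FALSE],
                truth[truth$sheet == s, , drop = FALSE]))
    out <- do.call(rbind, matched)
  } else {
    out <- match_one(results, truth)
  }
  if (is.null(out)) return(results[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Evaluate genotype calls against ground truth
#'
#' Builds the 3-class confusion matrix and, for each screening comparison,
#' the five metrics with Wilson CIs under the configured convention plus an
#' S-index ROC/AUC when scores are available.
#'
#' @param truth true genotype vector (Sbeta+ samples, labelled `"SBplus"`,
#'   are evaluated as SS, matching how the assay reports them).
#' @param calls predicted genotype vector (`"AA"`, `"AS"`, `"SS"`).
#' @param scores optional S-index vector for ROC analysis.
#' @param comparisons comparison set, as in [rater_summary()].
#' @param ci_convention,cohort_n,z passed to [binary_metrics()].
#' @return A list of class `call_evaluation`: `confusion`, `metrics`
#'   (data frame with a `comparison` column), `roc` (named list or NULL).
#' @export
evaluate_calls <- function(truth, calls, scores = NULL,
                           comparisons = screening_comparisons(),
                           ci_convention = "standard", cohort_n = NULL,
                           z = 1.96) {
  truth <- ifelse(truth == "SBplus", "SS", truth)
  labels <- sort(unique(c(truth, calls)))
  cm <- confusion_matrix(truth, calls, labels)
  metrics <- list()
  rocs <- list()
  for (cmp_name in names(comparisons)) {
    cmp <- comparisons[[cmp_name]]
    if (!is.null(cmp$restrict) && !all(cmp$restrict %in% labels)) next
    bc <- binarize(cm, intersect(cmp$positive, labels), restrict = cmp$restrict)
    n_cmp <- with(bc, tp + fp + tn + fn)
    bm <- binary_metrics(bc, ci_convention = ci_convention,
                         cohort_n = cohort_n %||% n_cmp, z = z)
    bm <- cbind(comparison = cmp_name, bm)
    metrics[[length(metrics) + 1L]] <- bm
    if (!is.null(scores)) {
      keep <- if (is.null(cmp$restrict)) rep(TRUE, length(truth))
      else truth %in% cmp$restrict
      pos <- truth[keep] %in% cmp$positive
      if (any(pos) && !all(pos))
        rocs[[cmp_name]] <- roc_auc(scores[keep], pos)
    }
  }
  structure(list(confusion = cm, metrics = do.call(rbind, metrics),
                 roc = if (length(rocs)) rocs else NULL),
            class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted):\n")
  print(unclass(x$confusion))
  cat("\nScreening metrics:\n")
  df <- x$metrics
  df$estimate <- sprintf("%.1f%%", 100 * df$estimate)
  df$ci <- sprintf("%.1f-%.1f%%", 100 * df$lower, 100 * df$upper)
  print(df[, c("comparison", "metric", "estimate", "ci", "n_eff")],
        row.names = FALSE)
  if (!is.null(x$roc)) {
    cat("\nROC AUC:\n")
    for (nm in names(x$roc))
      cat(sprintf("  %s: %.4f\n", nm, x$roc[[nm]]$auc))
  }
  invisible(x)
}

#' Evaluate a results CSV against a truth CSV
#'
#' Joins per-stain results to ground truth (by `stain_id` when the ids
#' match, otherwise by center proximity), then runs [evaluate_calls()].
#' When the results carry no `call` column, thresholds are fitted on the
#' matched data first (resubstitution).
#'
#' @param results_csv per-stain results CSV from [run_analyze()].
#' @param truth_csv ground-truth CSV from [run_simulate()].
#' @param config a [run_config()].
#' @param out_dir optional directory for the report files (metrics CSV,
#'   confusion CSV, plain-text report with provenance).
#' @return The [evaluate_calls()] result, with the matched table in
#'   `$matched` and unmatched-id messages in `attr(, "warnings")`.
#' @export
run_evaluate <- function(results_csv, truth_csv, config = run_config(),
                         out_dir = NULL) {
  results <- utils::read.csv(results_csv, stringsAsFactors = FALSE)
  truth <- utils::read.csv(truth_csv, stringsAsFactors = FALSE)
  if (nrow(truth) == 0) stop("empty truth table", call. = FALSE)
  warns <- character(0)
  if (all(results$stain_id %in% truth$stain_id) && nrow(results) > 0) {
    matched <- merge(results, truth[, c("stain_id", "genotype", "percent_hbs",
                                        "hb_conc")], by = "stain_id")
  } else {
    matched <- match_detections(results, truth)
    if ("truth_id" %in% names(matched)) matched$stain_id <- matched$truth_id
  }
  if (nrow(matched) == 0) stop("no results matched the truth", call. = FALSE)
  dropped <- setdiff(truth$stain_id, matched$stain_id)
  if (length(dropped))
    warns <- c(warns, paste("unmatched truth ids excluded:",
                            paste(dropped, collapse = ", ")))
  if (!"call" %in% names(matched)) {
    th <- config$thresholds %||%
      fit_thresholds(matched$s_index, ifelse(matched$genotype == "SBplus",
                                             "SS", matched$genotype))
    matched$call <- classify_s_index(matched$s_index, th)
  }
  ev <- evaluate_calls(matched$genotype, matched$call,
                       scores = matched$s_index,
                       ci_convention = config$ci_convention)
  ev$matched <- matched
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(ev$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(ev$confusion)),
                     file.path(out_dir, "confusion.csv"))
    rep_path <- file.path(out_dir, "report.txt")
    con <- file(rep_path, "w")
    writeLines(provenance_block(config, config$seed), con)
    writeLines("", con)
    sink(con); print(ev); sink()
    close(con)
  }
  structure(ev, warnings = warns)
}

#' Load a per-sample score table, if one is available
#'
#' Cohort-level figures (confusion-matrix cells, per-rater mean +/- SD
#' tables, the published kappa and AUC values) can only be recomputed from
#' per-sample data. This helper loads such a table when the user supplies
#' one (CSV with at least `s_index` and `genotype` columns) and returns
#' `NULL` with a message when none is available, so pipelines can skip
#' those recomputations gracefully.
#'
#' @param path CSV path, or `NULL`.
#' @return Data frame, or `NULL` when the file is absent or lacks the
#'   required columns.
#' @export
read_sample_scores <- function(path = NULL) {
  if (is.null(path) || !file.exists(path)) {
    message("no per-sample score table available; cohort-level recomputations skipped")
    return(NULL)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("s_index", "genotype") %in% names(df))) {
    message("per-sample table lacks s_index/genotype columns; skipped")
    return(NULL)
  }
  df
}
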
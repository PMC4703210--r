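#' S-index genotype thresholds
#'
#' Two cutoffs partition the S-index axis into the three screening classes:
#' values at or below `tau_any_s` are called HbAA, values above `tau_ss` are
#' called HbSS, and the band between them HbAS. Boundary values resolve to
#' the less severe class.
#'
#' @param tau_any_s cutoff separating AA from any-HbS (AS, SS).
#' @param tau_ss cutoff separating AS from SS.
#' @param c_cutoff optional C-index cutoff separating SC from AS.
#' @return A `thresholds` list.
#' @export
thresholds <- function(tau_any_s, tau_ss, c_cutoff = NA_real_) {
  if (!is.finite(tau_any_s) || !is.finite(tau_ss) || tau_any_s <= 0 ||
      tau_ss <= 0)
    stop("cutoffs must be positive and finite", call. = FALSE)
  if (tau_any_s >= tau_ss)
    stop("need tau_any_s < tau_ss", call. = FALSE)
  structure(list(tau_any_s = tau_any_s, tau_ss = tau_ss, c_cutoff = c_cutoff),
            class = "thresholds")
}

#' Classify S-index values into HbAA / HbAS / HbSS
#'
#' Severity is ordered AA < AS < SS and ties at a cutoff resolve to the
#' less severe class, so the call is monotone in the score. Note that
#' S-beta+-thalassemia samples, whose HbS content exceeds 60%, fall in the
#' SS band and are reported as SS.
#'
#' @param s S-index value(s), non-negative and finite.
#' @param th a [thresholds()] object.
#' @return Character vector of calls in `{"AA", "AS", "SS"}`.
#' @export
classify_s_index <- function(s, th) {
  stopifnot(inherits(th, "thresholds"))
  if (any(!is.finite(s)) || any(s < 0))
    stop("S-index values must be finite and non-negative", call. = FALSE)
  ifelse(s <= th$tau_any_s, "AA", ifelse(s <= th$tau_ss, "AS", "SS"))
}

# Youden's J over candidate cutoffs (midpoints of adjacent distinct sorted
# scores); positives are scores strictly above the cutoff. Ties in J break
# toward the higher cutoff (higher specificity).
best_youden_cutoff <- function(scores, positive) {
  u <- sort(unique(scores))
  if (length(u) < 2)
    stop("cannot place a cutoff: all scores identical", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  n_pos <- sum(positive); n_neg <- sum(!positive)
  j <- vapply(cand, function(cc) {
    sens <- sum(positive & scores > cc) / n_pos
    spec <- sum(!positive & scores <= cc) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

#' Fit S-index thresholds from labelled scores
#'
#' Each cutoff maximizes Youden's J (sensitivity + specificity - 1) over
#' midpoints between adjacent sorted scores: `tau_any_s` for the AA-vs-rest
#' split (positives = any HbS) and `tau_ss` for the SS-vs-rest split. Ties
#' break toward higher specificity (the higher cutoff).
#'
#' @param scores numeric S-index values.
#' @param labels genotype labels (`"AA"`, `"AS"`, `"SS"`; other labels with
#'   HbS, e.g. `"SBplus"`, count as positive for both splits).
#' @return A [thresholds()] object.
#' @export
fit_thresholds <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2)
    stop("threshold fitting needs at least 2 classes", call. = FALSE)
  any_s <- labels != "AA"
  ss_like <- labels %in% c("SS", "SBplus")
  tau_any <- best_youden_cutoff(scores, any_s)
  tau_ss <- if (any(ss_like) && !all(ss_like))
    best_youden_cutoff(scores, ss_like)
  else tau_any + diff(range(scores))  # degenerate: no SS split available
  if (tau_ss <= tau_any) tau_ss <- tau_any + .Machine$double.eps * tau_any * 4
  thresholds(tau_any, tau_ss)
}

#' Classify the C-index into HbSC vs HbAS
#'
#' Among samples in the carrier-like S-index band, a low C-index indicates
#' HbSC: HbSC samples typically carry less total hemoglobin than HbAS
#' carriers, and the C-index scales with total Hb. The score is first
#' normalized by the cutoff; normalized values below 1 are called SC, and
#' the boundary (exactly 1) resolves to AS.
#'
#' @param c_value C-index value(s), non-negative.
#' @param c_cutoff positive C-index cutoff.
#' @return Character vector of extended calls in `{"SC", "AS"}`.
#' @export
classify_c_index <- function(c_value, c_cutoff) {
  if (!is.finite(c_cutoff) || c_cutoff <= 0)
    stop("c_cutoff must be positive", call. = FALSE)
  if (any(!is.finite(c_value)) || any(c_value < 0))
    stop("C-index values must be finite and non-negative", call. = FALSE)
  ifelse(c_value / c_cutoff < 1, "SC", "AS")
}

#' Fit a C-index cutoff at full SC sensitivity
#'
#' Chooses the smallest cutoff that still calls every SC sample SC
#' (normalized value below 1): the midpoint between the largest SC score
#' and the smallest AS score above it. This is the screening regime the
#' C-index is meant for - never miss SC, accept false positives among AS.
#'
#' @param c_values numeric C-index scores.
#' @param labels matching labels, `"SC"` or `"AS"`.
#' @return The cutoff (numeric scalar).
#' @export
fit_c_cutoff <- function(c_values, labels) {
  stopifnot(length(c_values) == length(labels))
  if (!any(labels == "SC") || !any(labels == "AS"))
    stop("need both SC and AS samples to fit a cutoff", call. = FALSE)
  max_sc <- max(c_values[labels == "SC"])
  above <- c_values[labels == "AS" & c_values > max_sc]
  if (length(above)) (max_sc + min(above)) / 2 else max_sc * 1.001
}

#' Linear calibration of S-index to %HbS
#'
#' Ordinary least squares of %HbS on S-index over dilution-series style
#' pairs. The residual SD (the SD of predicted minus true %HbS over the
#' fitting set) quantifies how precisely the stain readout recovers the
#' HbS fraction.
#'
#' @param s_index S-index measurements.
#' @param percent_hbs matching true %HbS values.
#' @return A list of class `calibration_model` with `slope` (%HbS per unit
#'   S-index), `intercept` (%HbS) and `residual_sd` (%HbS).
#' @export
fit_hbs_calibration <- function(s_index, percent_hbs) {
  stopifnot(length(s_index) == length(percent_hbs))
  if (length(s_index) < 3)
    stop("calibration needs at least 3 pairs", call. = FALSE)
  if (length(unique(s_index)) < 2)
    stop("degenerate design: all S-index values equal", call. = FALSE)
  fit <- stats::lm(percent_hbs ~ s_index)
  pred <- stats::fitted(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = stats::sd(pred - percent_hbs)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %%HbS = %.3f * S-index + %.3f (residual SD %.2f %%HbS)\n",
              x$slope, x$intercept, x$residual_sd))
  invisible(x)
}

#' Predict %HbS from an S-index
#'
#' @param model a [fit_hbs_calibration()] result.
#' @param s S-index value(s), finite.
#' @return Predicted %HbS, clamped to `[0, 100]`.
#' @export
predict_percent_hbs <- function(model, s) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(s))) stop("S-index must be finite", call. = FALSE)
  pmax(0, pmin(100, model$slope * s + model$intercept))
}

#' Serialize thresholds and calibration to a plain-text config
#'
#' Writes a small versioned JSON (or YAML) document so that numeric cutoffs
#' fitted on one cohort can be pinned and reused reproducibly.
#'
#' @param th a [thresholds()] object, or `NULL`.
#' @param calibration a `calibration_model`, or `NULL`.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(th = NULL, calibration = NULL, path) {
  doc <- list(schema = "stainscore/model-config", version = 1L)
  if (!is.null(th)) doc$thresholds <- unclass(th)
  if (!is.null(calibration)) doc$calibration <- unclass(calibration)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else stop("unsupported config format: .", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format: .", ext, call. = FALSE)
  if (!identical(doc$schema, "stainscore/model-config"))
    stop("not a stainscore model config", call. = FALSE)
  out <- list(thresholds = NULL, calibration = NULL)
  if (!is.null(doc$thresholds))
    out$thresholds <- thresholds(doc$thresholds$tau_any_s,
                                 doc$thresholds$tau_ss,
                                 doc$thresholds$c_cutoff %||% NA_real_)
  if (!is.null(doc$calibration))
    out$calibration <- structure(doc$calibration[c("slope", "intercept",
                                                   "residual_sd")],
                                 class = "calibration_model")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
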
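#' K-class confusion matrix
#'
#' Rows are true classes, columns predicted classes. Aggregation over
#' raters is additive: the matrix of concatenated rater calls equals the
#' elementwise sum of per-rater matrices.
#'
#' @param truth,predicted equal-length vectors of class labels.
#' @param labels ordered class names; every value of `truth` and
#'   `predicted` must be among them.
#' @return An integer `labels x labels` matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, labels = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (!all(c(truth, predicted) %in% labels))
    stop("labels outside the declared set", call. = FALSE)
  tt <- factor(truth, levels = labels)
  pp <- factor(predicted, levels = labels)
  m <- table(truth = tt, predicted = pp)
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(truth = labels, predicted = labels))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Collapse a confusion matrix to binary screening counts
#'
#' `positive_classes` must be a nonempty proper subset of the labels. For a
#' two-class comparison restricted to a subset of classes (e.g. AS vs SS),
#' first subset the matrix with `restrict`.
#'
#' @param cm a [confusion_matrix()].
#' @param positive_classes character vector of positive class names.
#' @param restrict optional character vector: drop all other true and
#'   predicted classes before binarizing.
#' @return A list of class `binary_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
binarize <- function(cm, positive_classes, restrict = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  labels <- rownames(cm)
  if (!is.null(restrict)) {
    keep <- labels %in% restrict
    cm <- cm[keep, keep, drop = FALSE]
    labels <- rownames(cm)
  }
  if (length(positive_classes) == 0 || !all(positive_classes %in% labels) ||
      all(labels %in% positive_classes))
    stop("positive_classes must be a nonempty proper subset of the labels",
         call. = FALSE)
  pos <- labels %in% positive_classes
  structure(list(tp = sum(cm[pos, pos]), fn = sum(cm[pos, !pos]),
                 fp = sum(cm[!pos, pos]), tn = sum(cm[!pos, !pos])),
            class = "binary_counts")
}

#' Wilson score interval for a binomial proportion
#'
#' Inverts the score test: center `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, clamped to `[0, 1]`.
#' `z` defaults to 1.96 (the conventional two-decimal critical value) rather
#' than the full-precision normal quantile; both are supported.
#'
#' @param p_hat observed proportion in `[0, 1]`.
#' @param n_eff effective sample size (at least 1).
#' @param z critical value.
#' @return A list of class `wilson_interval` with `p_hat`, `n_eff`, `z`,
#'   `lower`, `upper`.
#' @export
wilson_interval <- function(p_hat, n_eff, z = 1.96) {
  if (!is.finite(p_hat) || p_hat < 0 || p_hat > 1)
    stop("p_hat must lie in [0, 1]", call. = FALSE)
  if (!is.finite(n_eff) || n_eff < 1)
    stop("n_eff must be at least 1", call. = FALSE)
  denom <- 1 + z^2 / n_eff
  center <- (p_hat + z^2 / (2 * n_eff)) / denom
  hw <- z * sqrt(p_hat * (1 - p_hat) / n_eff + z^2 / (4 * n_eff^2)) / denom
  structure(list(p_hat = p_hat, n_eff = n_eff, z = z,
                 lower = max(0, center - hw), upper = min(1, center + hw)),
            class = "wilson_interval")
}

#' @export
print.wilson_interval <- function(x, ...) {
  cat(sprintf("%.1f%% (95%% CI: %.1f-%.1f%%), n = %g\n", 100 * x$p_hat,
              100 * x$lower, 100 * x$upper, x$n_eff))
  invisible(x)
}

#' Screening metrics with Wilson confidence intervals
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, positive and
#' negative predictive values and accuracy, each with a Wilson 95% CI. Two
#' interval conventions are provided: `"standard"` uses each metric's own
#' denominator as the interval's n; `"cohort_total"` uses the total number
#' of samples in the comparison for every metric, a convention found in some
#' published screening evaluations (supply it via `cohort_n`, defaulting to
#' the count total). Metrics with a zero denominator are returned as `NA`
#' and flagged in the `defined` column rather than silently zeroed.
#'
#' @param bc a [binarize()] result (or list with tp, fp, tn, fn).
#' @param ci_convention `"standard"` or `"cohort_total"`.
#' @param cohort_n total comparison size used under `"cohort_total"`.
#' @param z critical value for the intervals.
#' @return Data frame with columns `metric`, `estimate`, `lower`, `upper`,
#'   `n_eff`, `defined`.
#' @export
binary_metrics <- function(bc, ci_convention = c("standard", "cohort_total"),
                           cohort_n = NULL, z = 1.96) {
  ci_convention <- match.arg(ci_convention)
  with(bc, {
    total <- tp + fp + tn + fn
    if (total <= 0) stop("empty counts", call. = FALSE)
    if (is.null(cohort_n)) cohort_n <- total
    num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn,
             accuracy = tp + tn)
    den <- c(sensitivity = tp + fn, specificity = fp + tn, ppv = tp + fp,
             npv = tn + fn, accuracy = total)
    rows <- lapply(names(num), function(m) {
      if (den[[m]] == 0)
        return(data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, n_eff = NA_real_, defined = FALSE))
      p <- num[[m]] / den[[m]]
      n_eff <- if (ci_convention == "cohort_total") cohort_n else den[[m]]
      ci <- wilson_interval(p, n_eff, z = z)
      data.frame(metric = m, estimate = p, lower = ci$lower, upper = ci$upper,
                 n_eff = n_eff, defined = TRUE)
    })
    do.call(rbind, rows)
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' Every distinct score is swept as a threshold with "positive" meaning
#' score strictly above it; the curve is completed with the (0,0) and (1,1)
#' endpoints and the AUC computed by the trapezoidal rule, which equals the
#' Mann-Whitney statistic with ties weighted 1/2.
#'
#' @param scores numeric scores; higher means more disease-like.
#' @param labels logical (or coercible) positive-class indicators; both
#'   classes must be present.
#' @return A list of class `roc_curve` with `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(labels)))
    stop("scores and binary labels must align", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores > t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores > t) / n_neg, numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr, -Inf), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for `n` subjects each rated by the same
#' number `m >= 2` of raters: `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar`
#' is the mean over subjects of the pairwise agreement and `Pe` the sum of
#' squared category marginals. Every subject must carry the same number of
#' non-missing ratings (no generalized weighting for unbalanced panels).
#'
#' @param ratings subjects x raters matrix (or data frame) of categorical
#'   calls.
#' @param categories optional category set; defaults to the values present.
#' @return Fleiss' kappa (scalar). Exactly 1 when all raters agree on all
#'   subjects and at least two categories are used; `NaN` if every rating
#'   in the table is the single same category (no chance correction
#'   possible).
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) stop("need at least 2 raters", call. = FALSE)
  if (any(is.na(ratings)))
    stop("every subject must be rated by every rater", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  if (!all(ratings %in% categories))
    stop("ratings outside the declared category set", call. = FALSE)
  n <- nrow(ratings); m <- ncol(ratings)
  counts <- t(apply(ratings, 1, function(r)
    tabulate(factor(r, levels = categories), nbins = length(categories))))
  if (length(categories) == 1L) counts <- matrix(m, n, 1)
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * m)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

#' Per-rater performance summary
#'
#' For a panel of raters who all scored the same subjects, computes each
#' rater's screening metrics for each requested comparison, then the
#' across-rater mean and SD of every metric - the "mean +/- SD over n
#' raters" presentation used for visual-scoring panels.
#'
#' @param truth common true-genotype vector.
#' @param calls list (one element per rater) of predicted-genotype vectors
#'   aligned with `truth`.
#' @param comparisons named list; each element is a list with elements
#'   `positive` (character vector) and optional `restrict`. Defaults to the
#'   three screening comparisons: any HbS vs AA, SS vs rest, SS vs AS.
#' @param ci_convention,cohort_n passed to [binary_metrics()].
#' @return Data frame with columns `comparison`, `metric`, per-rater
#'   estimates (`rater_1`, ...), `mean`, `sd`.
#' @export
rater_summary <- function(truth, calls, comparisons = screening_comparisons(),
                          ci_convention = "standard", cohort_n = NULL) {
  if (length(calls) < 2) stop("need at least 2 raters", call. = FALSE)
  ok <- vapply(calls, function(x) length(x) == length(truth), logical(1))
  if (!all(ok)) stop("every rater must score the same subjects", call. = FALSE)
  labels <- sort(unique(c(truth, unlist(calls))))
  rows <- list()
  for (cmp_name in names(comparisons)) {
    cmp <- comparisons[[cmp_name]]
    per_rater <- sapply(calls, function(pred) {
      cm <- confusion_matrix(truth, pred, labels)
      bc <- binarize(cm, cmp$positive, restrict = cmp$restrict)
      bm <- binary_metrics(bc, ci_convention = ci_convention,
                           cohort_n = cohort_n)
      stats::setNames(bm$estimate, bm$metric)
    })
    for (metric in rownames(per_rater)) {
      est <- per_rater[metric, ]
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp_name, metric = metric,
        t(stats::setNames(est, paste0("rater_", seq_along(est)))),
        mean = mean(est), sd = stats::sd(est))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The three standard screening comparisons
#'
#' Any-HbS detection (AA vs AS+SS), disease detection (SS vs AA+AS), and
#' disease vs trait (SS vs AS, restricted to those two classes).
#'
#' @return Named list of comparison definitions for [rater_summary()] and
#'   [evaluate_calls()].
#' @export
screening_comparisons <- function() {
  list(any_hbs = list(positive = c("AS", "SS"), restrict = NULL),
       ss_vs_rest = list(positive = "SS", restrict = NULL),
       ss_vs_as = list(positive = "SS", restrict = c("AS", "SS")))
}
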
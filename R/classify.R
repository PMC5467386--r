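#' The three IFL severity classes
#'
#' @return Character vector `c("NIFL", "IFL1", "IFL2")`: non-flow-limited,
#'   mild, and severe inspiratory flow limitation.
#' @export
ifl_classes <- function() c("NIFL", "IFL1", "IFL2")

ifl_factor <- function(x) {
  f <- factor(as.character(x), levels = ifl_classes())
  if (anyNA(f))
    stop("labels must be one of NIFL, IFL1, IFL2", call. = FALSE)
  f
}

#' Construct a cut-off set for one feature method
#'
#' Two thresholds split a feature score into the three severity classes.
#' For methods whose score increases with severity (the polynomial
#' residuals) `t_mild <= t_severe`; for decreasing methods (the flatness
#' index, where flat means severe) `t_mild >= t_severe`. Boundary values
#' belong to the less severe side for increasing methods and to the more
#' severe side for decreasing ones, matching the `<=` conventions of the
#' shipped defaults.
#'
#' @param method One of `"fi"`, `"order1"`, `"order2"`, `"order3"`, `"w3"`.
#' @param direction `"increasing"` or `"decreasing"` (with severity).
#' @param t_mild Threshold separating NIFL from IFL1.
#' @param t_severe Threshold separating IFL1 from IFL2.
#' @return An object of class `cutoff_set`.
#' @export
cutoff_set <- function(method, direction = c("increasing", "decreasing"),
                       t_mild, t_severe) {
  method <- match.arg(method, c("fi", "order1", "order2", "order3", "w3"))
  direction <- match.arg(direction)
  if (!all(is.finite(c(t_mild, t_severe))))
    stop("thresholds must be finite", call. = FALSE)
  if (direction == "increasing" && t_mild > t_severe)
    stop("increasing direction requires t_mild <= t_severe", call. = FALSE)
  if (direction == "decreasing" && t_mild < t_severe)
    stop("decreasing direction requires t_mild >= t_severe", call. = FALSE)
  structure(list(method = method, direction = direction,
                 t_mild = t_mild, t_severe = t_severe),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set %s (%s with severity): NIFL|IFL1 at %g, IFL1|IFL2 at %g>\n",
              x$method, x$direction, x$t_mild, x$t_severe))
  invisible(x)
}

#' Shipped default cut-offs
#'
#' Reads the package's frozen per-method decision intervals (flatness
#' index: NIFL > 0.175, IFL2 <= 0.095; weighted third order: NIFL <= 0.87,
#' IFL2 > 2.7; and so on) from the configuration file shipped under
#' `extdata`.
#'
#' @param method Optional method name; when given, the single `cutoff_set`
#'   is returned instead of the full list.
#' @return A named list of [cutoff_set()] objects, or one `cutoff_set`.
#' @export
default_cutoffs <- function(method = NULL) {
  path <- system.file("extdata", "cutoffs_default.yaml", package = "iflscan")
  cuts <- read_cutoffs(path)
  if (is.null(method)) cuts else {
    method <- match.arg(method, names(cuts))
    cuts[[method]]
  }
}

#' Read cut-off sets from a YAML file
#'
#' @param path YAML file with one entry per method:
#'   `method: {direction, t_mild, t_severe}`.
#' @return Named list of [cutoff_set()] objects.
#' @export
read_cutoffs <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cut-off file '%s' does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(m)
    cutoff_set(m, raw[[m]]$direction, raw[[m]]$t_mild, raw[[m]]$t_severe))
  names(out) <- names(raw)
  out
}

#' Write cut-off sets to a YAML file
#'
#' @param cutoffs A `cutoff_set` or named list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cutoffs <- function(cutoffs, path) {
  if (inherits(cutoffs, "cutoff_set"))
    cutoffs <- stats::setNames(list(cutoffs), cutoffs$method)
  out <- lapply(cutoffs, function(cs)
    list(direction = cs$direction, t_mild = cs$t_mild, t_severe = cs$t_severe))
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Classify feature scores into IFL severity classes
#'
#' The decision intervals partition the real line. For increasing methods:
#' `score <= t_mild` is NIFL, `score <= t_severe` is IFL1, above is IFL2.
#' For decreasing methods: `score > t_mild` is NIFL, `score > t_severe` is
#' IFL1, at or below is IFL2.
#'
#' @param score Numeric vector of finite feature scores.
#' @param cutoffs A [cutoff_set()].
#' @return Factor with levels `NIFL, IFL1, IFL2`, one label per score.
#' @export
classify_breath <- function(score, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (!is.numeric(score) || anyNA(score) || !all(is.finite(score)))
    stop("'score' must be finite (no NA/NaN)", call. = FALSE)
  lab <- if (cutoffs$direction == "increasing") {
    ifelse(score <= cutoffs$t_mild, "NIFL",
           ifelse(score <= cutoffs$t_severe, "IFL1", "IFL2"))
  } else {
    ifelse(score > cutoffs$t_mild, "NIFL",
           ifelse(score > cutoffs$t_severe, "IFL1", "IFL2"))
  }
  factor(lab, levels = ifl_classes())
}

# Best threshold for a two-class split: candidates are midpoints between
# consecutive distinct scores; maximises sensitivity + specificity; ties go
# to the smaller threshold. `severe_high` says whether the more severe
# class has the higher scores.
best_threshold <- function(s_less, s_more, severe_high) {
  s <- sort(unique(c(s_less, s_more)))
  if (length(s) < 2L) return(s[1L])
  cand <- (s[-length(s)] + s[-1L]) / 2
  j <- vapply(cand, function(tt) {
    if (severe_high) mean(s_more > tt) + mean(s_less <= tt)
    else mean(s_more <= tt) + mean(s_less > tt)
  }, numeric(1))
  cand[which.max(j)]   # which.max returns the first (smallest) maximiser
}

#' Calibrate cut-offs from labelled feature scores
#'
#' Reproduces the ROC cut-point selection used to derive the shipped
#' defaults: the direction is set by comparing the NIFL and IFL2 median
#' scores, then each threshold is chosen on the corresponding adjacent-pair
#' two-class problem (NIFL vs IFL1 for `t_mild`, IFL1 vs IFL2 for
#' `t_severe`) to maximise sensitivity + specificity. Candidate thresholds
#' are midpoints between consecutive distinct scores; ties break toward the
#' smaller threshold.
#'
#' @param scores Numeric vector of feature scores.
#' @param labels Severity labels (`NIFL`/`IFL1`/`IFL2`), same length.
#' @param method Method name recorded in the result. Default `"w3"`.
#' @return A [cutoff_set()].
#' @export
calibrate_cutoffs <- function(scores, labels, method = "w3") {
  labels <- ifl_factor(labels)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length", call. = FALSE)
  n <- table(labels)
  if (any(n < 2L))
    stop("calibration requires at least 2 breaths in each of the three classes",
         call. = FALSE)
  s <- split(scores, labels)
  severe_high <- stats::median(s$IFL2) > stats::median(s$NIFL)
  t_mild <- best_threshold(s$NIFL, s$IFL1, severe_high)
  t_severe <- best_threshold(s$IFL1, s$IFL2, severe_high)
  # Degenerate middle class: collapse crossed thresholds to keep intervals
  # a partition.
  if (severe_high && t_mild > t_severe) {
    warning("calibrated thresholds crossed; collapsing the IFL1 interval")
    t_severe <- t_mild
  }
  if (!severe_high && t_mild < t_severe) {
    warning("calibrated thresholds crossed; collapsing the IFL1 interval")
    t_severe <- t_mild
  }
  cutoff_set(method, if (severe_high) "increasing" else "decreasing",
             t_mild, t_severe)
}

#' Two-class ROC curve and AUC
#'
#' The area under the curve equals the normalised Mann-Whitney U statistic:
#' the probability that a positive item scores above a negative one, ties
#' counted half. Curve points are evaluated at every distinct score with
#' the rule "score >= threshold is called positive".
#'
#' @param scores Numeric feature scores.
#' @param positive Logical (or 0/1) vector marking the positive class.
#' @return An object of class `roc_curve` with fields `thresholds`,
#'   `sensitivity`, `specificity` and `auc`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive) || anyNA(positive))
    stop("'positive' must be a logical vector matching 'scores'", call. = FALSE)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)               # midranks handle ties
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores))
  sens <- vapply(th, function(tt) mean(scores[positive] >= tt), numeric(1))
  spec <- vapply(th, function(tt) mean(scores[!positive] < tt), numeric(1))
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.3f over %d thresholds>\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}
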
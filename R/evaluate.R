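# Round half away from zero, as printed summary tables do.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

cobweb_arm_names <- function() {
  cls <- ifl_classes()
  prs <- expand.grid(to = cls, from = cls, stringsAsFactors = FALSE)
  prs <- prs[prs$from != prs$to, c("from", "to")]
  ord <- order(match(prs$from, cls), match(prs$to, cls))
  paste0(prs$from, "->", prs$to)[ord]
}

#' Three-class confusion summary
#'
#' Tallies the 3x3 confusion matrix (rows = true class, columns =
#' predicted) and derives the reporting quantities: per-class accuracy
#' (row-normalised diagonal), one-vs-rest sensitivity (TP rate, identical
#' to per-class accuracy) and specificity (TN rate), overall accuracy, and
#' the six cobweb misclassification arms (off-diagonal counts normalised by
#' the true-class size). Percentages are rounded half-up to two decimals.
#'
#' @param truth True labels (`NIFL`/`IFL1`/`IFL2`); every class must occur.
#' @param predicted Predicted labels, same length.
#' @return An object of class `confusion_summary` with fields `counts`,
#'   `per_class_accuracy`, `per_class_tp`, `per_class_tn`,
#'   `overall_accuracy`, `overall_accuracy_pct`, `cobweb` and `total`.
#' @export
confusion_summary <- function(truth, predicted) {
  truth <- ifl_factor(truth)
  predicted <- ifl_factor(predicted)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have the same length", call. = FALSE)
  counts <- unclass(table(truth, predicted))
  dimnames(counts) <- list(true = ifl_classes(), predicted = ifl_classes())
  rs <- rowSums(counts)
  if (any(rs == 0L))
    stop("every true class must contain at least one item", call. = FALSE)
  cs <- colSums(counts)
  total <- sum(counts)
  dg <- diag(counts)
  tn <- (total - rs - cs + dg) / (total - rs)
  arms <- counts / rs             # row-normalised; diagonal dropped below
  cob <- stats::setNames(numeric(6L), cobweb_arm_names())
  cls <- ifl_classes()
  for (a in cls) for (b in cls) if (a != b)
    cob[paste0(a, "->", b)] <- arms[a, b]
  structure(
    list(counts = counts,
         per_class_accuracy = dg / rs,
         per_class_tp = dg / rs,
         per_class_tn = tn,
         overall_accuracy = sum(dg) / total,
         overall_accuracy_pct = round_half_up(100 * sum(dg) / total, 2L),
         cobweb = cob,
         total = total),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Three-class confusion summary (n = %d)\n", x$total))
  print(x$counts)
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy_pct))
  cat("Per-class accuracy:",
      paste(sprintf("%s %.2f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  invisible(x)
}

#' Cobweb misclassification rates
#'
#' The six ordered-pair misclassification fractions (`NIFL->IFL1`,
#' `NIFL->IFL2`, `IFL1->NIFL`, `IFL1->IFL2`, `IFL2->NIFL`, `IFL2->IFL1`),
#' each the off-diagonal count divided by the true-class size. A uniform
#' random three-class classifier puts every arm near 1/3; the arms for a
#' class sum to one minus that class's accuracy.
#'
#' @param x A [confusion_summary()].
#' @return Named numeric vector of 6 fractions in \[0, 1\].
#' @export
cobweb_rates <- function(x) {
  stopifnot(inherits(x, "confusion_summary"))
  x$cobweb
}

#' Draw a cobweb (radar) misclassification plot
#'
#' Six axes, one per ordered misclassification pair, cropped at
#' `max_rate` = 0.5 from the centre (0 = no misclassification). A dashed
#' reference hexagon marks the 1/3 rate of a chance classifier.
#'
#' @param arms Named 6-vector from [cobweb_rates()], or a named list of
#'   such vectors to overlay several classifiers.
#' @param max_rate Axis crop. Default 0.5.
#' @param main Plot title.
#' @param cols Line colours, recycled over classifiers.
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_cobweb <- function(arms, max_rate = 0.5, main = "Misclassification cobweb",
                        cols = c("#D62728", "#1F77B4", "#2CA02C", "#9467BD",
                                 "#FF7F0E")) {
  if (!is.list(arms)) arms <- list(classifier = arms)
  nm <- cobweb_arm_names()
  ang <- pi / 2 - 2 * pi * (seq_len(6L) - 1L) / 6
  op <- graphics::par(mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.3, 1.3), axes = FALSE,
                 xlab = "", ylab = "", asp = 1, main = main)
  for (r in seq(0.1, max_rate, by = 0.1) / max_rate)
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey85")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey70")
  graphics::text(1.22 * cos(ang), 1.22 * sin(ang), nm, cex = 0.75)
  ref <- rep((1 / 3) / max_rate, 6L)
  graphics::polygon(ref * cos(ang), ref * sin(ang), border = "grey30",
                    lty = 2, lwd = 1.5)
  for (i in seq_along(arms)) {
    r <- pmin(arms[[i]][nm], max_rate) / max_rate
    graphics::polygon(r * cos(ang), r * sin(ang),
                      border = cols[(i - 1L) %% length(cols) + 1L], lwd = 2)
  }
  if (length(arms) > 1L || !is.null(names(arms)))
    graphics::legend("bottomright", legend = c(names(arms), "chance (1/3)"),
                     col = c(cols[seq_along(arms)], "grey30"),
                     lty = c(rep(1, length(arms)), 2), lwd = 2, cex = 0.7,
                     bty = "n")
  invisible(NULL)
}

#' Write the cobweb plot to an SVG file
#'
#' @param arms As in [plot_cobweb()].
#' @param path Output `.svg` path.
#' @param ... Passed to [plot_cobweb()].
#' @return Invisibly, `path`.
#' @export
write_cobweb_svg <- function(arms, path, ...) {
  grDevices::svg(path, width = 7, height = 6.5)
  on.exit(grDevices::dev.off())
  plot_cobweb(arms, ...)
  invisible(path)
}

#' Write a metrics JSON file for one classifier
#'
#' @param summary A [confusion_summary()].
#' @param method Method name recorded in the file.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(summary, method, path) {
  stopifnot(inherits(summary, "confusion_summary"))
  out <- list(
    method = method,
    n = summary$total,
    overall_accuracy_pct = summary$overall_accuracy_pct,
    per_class = lapply(stats::setNames(ifl_classes(), ifl_classes()),
                       function(cl) list(
                         accuracy_pct = round_half_up(
                           100 * summary$per_class_accuracy[[cl]], 2L),
                         tp_rate = summary$per_class_tp[[cl]],
                         tn_rate = summary$per_class_tn[[cl]])),
    cobweb = as.list(summary$cobweb)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
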
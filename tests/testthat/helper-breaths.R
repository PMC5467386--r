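# Shared fixtures, all built in code.

grid100 <- seq(0, 1, length.out = 100)

# A breath that is an exact polynomial on the normalized grid, affinely
# rescaled to [0, 1]. Returns the rescaled values together with the
# coefficients of the rescaled polynomial (computed by plain arithmetic,
# independent of any fitting code).
polynomial_breath <- function(coef) {
  k <- length(coef) - 1
  v <- as.numeric(outer(grid100, 0:k, `^`) %*% coef)
  lo <- min(v); rng <- max(v) - lo
  expected <- coef / rng
  expected[1] <- (coef[1] - lo) / rng
  list(values = (v - lo) / rng, coefficients = expected)
}

# Random non-constant breath values on the unit square.
random_breath_values <- function() {
  v <- stats::runif(100)
  (v - min(v)) / (max(v) - min(v))
}

# Half-sine inspiration samples (not yet normalized).
half_sine <- function(n = 40, amp = 1) amp * sin(pi * seq(0, 1, length.out = n))

# Independent weighted least-squares oracle: explicit normal equations.
normal_eq_coef <- function(values, k, w = rep(1, 100)) {
  X <- outer(grid100, 0:k, `^`)
  solve(t(X) %*% (w * X), t(X) %*% (w * values))[, 1]
}

# Write a two-column time,flow CSV and return its path.
write_flow_csv <- function(flow, fs, path = tempfile(fileext = ".csv"),
                           header = TRUE) {
  df <- data.frame(time = seq_along(flow - 1) / fs - 1 / fs, flow = flow)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = header)
  path
}

# Build truth/prediction label vectors realising given per-class diagonal
# counts (off-diagonal errors assigned arbitrarily; they do not affect
# accuracy figures).
labels_from_counts <- function(correct, class_sizes) {
  cls <- ifl_classes()
  truth <- rep(cls, class_sizes)
  pred <- character(0)
  for (i in seq_along(cls)) {
    wrong <- class_sizes[i] - correct[i]
    other <- cls[if (i == 1) 2 else 1]
    pred <- c(pred, rep(cls[i], correct[i]), rep(other, wrong))
  }
  list(truth = truth, pred = pred)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

# Run the installed CLI script; returns list(status, stdout, stderr).
run_cli <- function(args) {
  script <- system.file("cli", "iflscan.R", package = "iflscan")
  out <- tempfile(); err <- tempfile()
  status <- suppressWarnings(system2(
    rscript_bin(), c(shQuote(script), args), stdout = out, stderr = err,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
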
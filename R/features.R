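#' Flatness index of a normalized breath
#'
#' Root-mean-square deviation of the middle 50% of the breath (grid indices
#' 25-74, 0-based) from the mean over that window, divided by the window
#' mean. A perfectly flat mid-inspiratory plateau scores 0, so low values
#' indicate flow limitation; rounded breaths score high. `variant = "mad"`
#' replaces the RMS deviation with the mean absolute deviation.
#'
#' @param x A [normalized_breath()] or 100-value numeric vector.
#' @param variant `"rms"` (default) or `"mad"`.
#' @return An object of class `flatness_result` with fields `fi_value`,
#'   `window_mean`, `window`, `n_breaths` and `variant`.
#' @export
flatness_index <- function(x, variant = c("rms", "mad")) {
  variant <- match.arg(variant)
  b <- as_normalized_breath(x)
  win <- b$values[26:75]          # 0-based grid indices 25..74
  M <- mean(win)
  if (M <= .Machine$double.eps)
    stop("degenerate window: middle 50% of the breath is identically zero",
         call. = FALSE)
  D <- 1                          # single-breath curve
  dev <- switch(variant,
                rms = sqrt(mean((win - M)^2)),
                mad = mean(abs(win - M)))
  structure(
    list(fi_value = dev / (M * D), window_mean = M, window = c(0.25, 0.75),
         n_breaths = D, variant = variant),
    class = "flatness_result"
  )
}

# Design matrix for a degree-k polynomial on the 100-point grid.
poly_design <- function(grid, k) outer(grid, 0:k, `^`)

#' Fit a polynomial to a normalized breath
#'
#' Least-squares fit of a degree-`k` polynomial `S(i)` to the breath values
#' `F(i)` over the 100-point grid, minimising `sum w_i (S(i) - F(i))^2`.
#' The model is linear in the coefficients, so the fit is solved directly
#' by weighted linear least squares (QR); the result coincides with what an
#' iterative damped least-squares optimiser converges to, but is exact and
#' deterministic.
#'
#' @param x A [normalized_breath()] or 100-value numeric vector.
#' @param k Polynomial order, one of 1, 2, 3.
#' @param weights Optional [weight_profile()]; when absent all points have
#'   unit weight.
#' @return An object of class `polynomial_fit` with fields `order`,
#'   `coefficients` (a_0..a_k), `fitted` (100 values) and `weighted`.
#' @export
fit_polynomial <- function(x, k, weights = NULL) {
  if (!is.numeric(k) || length(k) != 1L || !(k %in% 1:3))
    stop("'k' must be 1, 2 or 3", call. = FALSE)
  b <- as_normalized_breath(x)
  w <- if (is.null(weights)) rep(1, 100L) else {
    stopifnot(inherits(weights, "weight_profile"))
    weights$weights
  }
  X <- poly_design(b$grid, k)
  sw <- sqrt(w)
  coef <- qr.coef(qr(X * sw), b$values * sw)
  names(coef) <- paste0("a", 0:k)
  structure(
    list(order = as.integer(k), coefficients = coef,
         fitted = as.numeric(X %*% coef), weighted = !is.null(weights)),
    class = "polynomial_fit"
  )
}

#' Unweighted absolute-residual sum of a polynomial fit
#'
#' The residual feature `R = sum_i |S(i) - F(i)|` over all 100 grid points
#' of the breath.
#'
#' @param fit A [fit_polynomial()] result produced from the same breath,
#'   without weights.
#' @param x The breath the fit was produced from.
#' @return An object of class `residual_feature` with fields `value`,
#'   `per_point` (100 absolute residuals) and `method`
#'   (`"order1"`/`"order2"`/`"order3"`).
#' @export
residual_sum <- function(fit, x) {
  stopifnot(inherits(fit, "polynomial_fit"))
  if (fit$weighted)
    stop("residual_sum() is defined for unweighted fits; see weighted_residual()",
         call. = FALSE)
  b <- as_normalized_breath(x)
  per_point <- abs(fit$fitted - b$values)
  structure(
    list(value = sum(per_point), per_point = per_point,
         method = paste0("order", fit$order)),
    class = "residual_feature"
  )
}

#' Endpoint/peak weighting profile for a breath
#'
#' Assigns weight `A` to the first and last grid points, `B` to the (first)
#' point attaining the breath maximum, and `C` elsewhere. When the maximum
#' falls on an endpoint, `B` takes precedence. Suggested ranges are
#' A in \[50, 100\], B in \[200, 400\], C = 1, with defaults A = 50, B = 200.
#'
#' @param x A [normalized_breath()] or 100-value numeric vector.
#' @param A Endpoint weight (> 0). Default 50.
#' @param B Peak weight (> 0). Default 200.
#' @param C Weight elsewhere (> 0). Default 1.
#' @return An object of class `weight_profile` with fields `A`, `B`, `C`,
#'   `weights` (100 values) and `peak_index` (1-based grid index of the
#'   first maximum).
#' @export
weight_profile <- function(x, A = 50, B = 200, C = 1) {
  if (any(!is.finite(c(A, B, C))) || any(c(A, B, C) <= 0))
    stop("weight factors A, B, C must be positive", call. = FALSE)
  b <- as_normalized_breath(x)
  peak <- which.max(b$values)     # first occurrence on plateaus
  w <- rep(C, 100L)
  w[c(1L, 100L)] <- A
  w[peak] <- B                    # B wins if the peak is an endpoint
  structure(list(A = A, B = B, C = C, weights = w, peak_index = peak),
            class = "weight_profile")
}

#' Check weight factors against the recommended ranges
#'
#' The shipped defaults come from a development set; factors outside
#' A in \[50, 100\], B in \[200, 400\], C = 1 are rejected unless
#' `unsafe = TRUE`.
#'
#' @param A,B,C Weight factors.
#' @param unsafe Allow out-of-range factors. Default `FALSE`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_weight_factors <- function(A, B, C, unsafe = FALSE) {
  if (any(!is.finite(c(A, B, C))) || any(c(A, B, C) <= 0))
    stop("weight factors A, B, C must be positive", call. = FALSE)
  if (!unsafe) {
    if (A < 50 || A > 100)
      stop("weight factor A outside the recommended range [50, 100]; set unsafe = TRUE to override",
           call. = FALSE)
    if (B < 200 || B > 400)
      stop("weight factor B outside the recommended range [200, 400]; set unsafe = TRUE to override",
           call. = FALSE)
    if (C != 1)
      stop("weight factor C is expected to be 1; set unsafe = TRUE to override",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Weighted absolute-residual feature
#'
#' Fits a degree-`k` polynomial with the weight profile entering the
#' squared-error objective, then sums the weighted absolute residuals
#' `R = sum_i W(i) |S(i) - F(i)|`. With `k = 3` and the default factors this
#' is the weighted third-order feature, the package's primary IFL score.
#'
#' @param x A [normalized_breath()] or 100-value numeric vector.
#' @param profile A [weight_profile()] built from this breath; defaults to
#'   `weight_profile(x)`.
#' @param k Polynomial order. Default 3.
#' @return A `residual_feature` with `method = "w3"` (or `"w<k>"`), plus a
#'   `fit` field holding the weighted [fit_polynomial()] result.
#' @export
weighted_residual <- function(x, profile = NULL, k = 3L) {
  b <- as_normalized_breath(x)
  if (is.null(profile)) profile <- weight_profile(b)
  stopifnot(inherits(profile, "weight_profile"))
  fit <- fit_polynomial(b, k, weights = profile)
  per_point <- abs(fit$fitted - b$values)
  structure(
    list(value = sum(profile$weights * per_point), per_point = per_point,
         method = if (k == 3L) "w3" else paste0("w", k), fit = fit),
    class = "residual_feature"
  )
}

#' All five per-breath IFL features
#'
#' @param x A [normalized_breath()] or 100-value numeric vector.
#' @param A,B,C Weight factors for the weighted third-order feature.
#' @param fi_variant Flatness-index variant, `"rms"` or `"mad"`.
#' @return Named numeric vector `c(fi, r1, r2, r3, rw3)`.
#' @export
breath_features <- function(x, A = 50, B = 200, C = 1, fi_variant = "rms") {
  b <- as_normalized_breath(x)
  r <- vapply(1:3, function(k) residual_sum(fit_polynomial(b, k), b)$value,
              numeric(1))
  c(fi = flatness_index(b, fi_variant)$fi_value,
    r1 = r[1L], r2 = r[2L], r3 = r[3L],
    rw3 = weighted_residual(b, weight_profile(b, A, B, C))$value)
}

#' Feature table for a set of breaths
#'
#' @param breaths A list of breaths (each a [normalized_breath()] or
#'   100-value vector) or a numeric matrix with one 100-value row per
#'   breath.
#' @param ... Passed to [breath_features()].
#' @return A data frame with columns `breath_id, fi, r1, r2, r3, rw3`.
#' @export
feature_table <- function(breaths, ...) {
  if (is.matrix(breaths))
    breaths <- lapply(seq_len(nrow(breaths)), function(i) breaths[i, ])
  feats <- t(vapply(breaths, breath_features, numeric(5), ...))
  data.frame(breath_id = seq_len(nrow(feats)), feats)
}
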
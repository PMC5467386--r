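#' Specification of one synthetic inspiratory breath
#'
#' Parameterises the four shape families emulating the severity taxonomy of
#' clinically observed inspiratory flow shapes: `sinusoidal` (rounded,
#' non-flow-limited), `mild_flat` (mildly flattened top), `multi_peak`
#' (rippled, 2-3 local maxima) and `flat_top` (broad severe plateau).
#'
#' @param family One of `"sinusoidal"`, `"mild_flat"`, `"flat_top"`,
#'   `"multi_peak"`.
#' @param plateau_level Clipping level as a fraction of the peak, in
#'   \[0.5, 1\]. Ignored by sinusoidal/multi_peak families.
#' @param plateau_width Fraction of the breath duration that is clipped, in
#'   \[0, 0.8\]. Must be 0 for `sinusoidal` and at least 0.4 for `flat_top`.
#' @param n_peaks Number of local maxima for `multi_peak` (1-3).
#' @param skew Time-warp exponent in \[0.7, 1.4\]; the base curve is
#'   `sin(pi * t^skew)`.
#' @param ripple_amp Ripple amplitude (fraction of peak) for `multi_peak`.
#' @param noise_sd Standard deviation of the additive band-limited Gaussian
#'   noise, as a fraction of peak amplitude.
#' @param time_inverted Reverse the breath in time.
#' @param seed Optional RNG seed making [generate_breath()] reproducible in
#'   isolation.
#' @return An object of class `breath_spec`.
#' @export
breath_spec <- function(family = c("sinusoidal", "mild_flat", "flat_top",
                                   "multi_peak"),
                        plateau_level = 0.8, plateau_width = 0, n_peaks = 2L,
                        skew = 1, ripple_amp = 0.065, noise_sd = 0,
                        time_inverted = FALSE, seed = NULL) {
  family <- match.arg(family)
  if (skew < 0.7 || skew > 1.4)
    stop("'skew' must lie in [0.7, 1.4]", call. = FALSE)
  if (plateau_level < 0.5 || plateau_level > 1)
    stop("'plateau_level' must lie in [0.5, 1]", call. = FALSE)
  if (plateau_width < 0 || plateau_width > 0.8)
    stop("'plateau_width' must lie in [0, 0.8]", call. = FALSE)
  if (!(n_peaks %in% 1:3))
    stop("'n_peaks' must be 1, 2 or 3", call. = FALSE)
  if (noise_sd < 0)
    stop("'noise_sd' must be non-negative", call. = FALSE)
  if (family == "sinusoidal" && plateau_width != 0)
    stop("sinusoidal breaths must have plateau_width 0", call. = FALSE)
  if (family == "flat_top" && plateau_width < 0.4)
    stop("flat_top breaths require plateau_width >= 0.4", call. = FALSE)
  if (family == "mild_flat" && plateau_width == 0)
    stop("mild_flat breaths require a positive plateau_width", call. = FALSE)
  structure(
    list(family = family, plateau_level = plateau_level,
         plateau_width = plateau_width, n_peaks = as.integer(n_peaks),
         skew = skew, ripple_amp = ripple_amp, noise_sd = noise_sd,
         time_inverted = isTRUE(time_inverted), seed = seed),
    class = "breath_spec"
  )
}

# Band-limited Gaussian perturbation: white noise smoothed with a Gaussian
# kernel (sd in grid samples), rescaled to the requested sd. Emulates noise
# that has passed the 2 Hz acquisition low-pass: per-breath noise on the
# normalized grid is smooth, never white.
smooth_noise <- function(n, sd, kernel_sd = 6) {
  half <- 4L * ceiling(kernel_sd)
  e <- stats::rnorm(n + 2L * half)
  k <- stats::dnorm(seq(-half, half), 0, kernel_sd)
  k <- k / sum(k)
  s <- stats::filter(e, k, sides = 2L)
  s <- as.numeric(s[(half + 1L):(half + n)])
  s / stats::sd(s) * sd
}

# Raised-cosine clipping mask: 1 over the centred plateau window, smooth
# shoulders of width `shoulder`, 0 outside. Smooth shoulders avoid
# grid-aligned constant maxima that make peak tie-breaking pathological.
clip_mask <- function(t, width, shoulder = 0.08) {
  d <- abs(t - 0.5)
  ifelse(d <= width / 2, 1,
         ifelse(d <= width / 2 + shoulder,
                0.5 * (1 + cos(pi * (d - width / 2) / shoulder)), 0))
}

severity_label <- function(spec) {
  if (spec$family == "sinusoidal") return("NIFL")
  if (spec$plateau_level < 0.85 && spec$plateau_width >= 0.4) return("IFL2")
  "IFL1"
}

#' Generate one labelled synthetic breath
#'
#' Builds `sin(pi * t^skew)` on the 100-point grid, applies the
#' family-specific deformation (soft clipping at `plateau_level` over a
#' centred window for the flattened families; low-amplitude ripple with
#' `n_peaks` local maxima for `multi_peak`), optionally reverses time, adds
#' band-limited Gaussian noise, and renormalizes to \[0, 1\]. Severity
#' labels follow the families: sinusoidal is NIFL; a breath clipped below
#' 85% of peak over at least 40% of its duration is IFL2; every other
#' deformation is IFL1. Deterministic given `spec$seed` (or the current RNG
#' state when no seed is set).
#'
#' @param spec A [breath_spec()].
#' @return List with elements `breath` (a [normalized_breath()]) and
#'   `label` (factor, one of `NIFL`/`IFL1`/`IFL2`).
#' @export
generate_breath <- function(spec) {
  stopifnot(inherits(spec, "breath_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
  }
  t <- seq(0, 1, length.out = 100L)
  v <- sin(pi * t^spec$skew)
  if (spec$family %in% c("mild_flat", "flat_top")) {
    m <- clip_mask(t, spec$plateau_width)
    v <- v - m * pmax(v - spec$plateau_level, 0)
  }
  if (spec$family == "multi_peak")
    v <- v + spec$ripple_amp * sin(pi * t) * cos(2 * pi * spec$n_peaks * t)
  if (spec$time_inverted) v <- rev(v)
  if (spec$noise_sd > 0) v <- v + smooth_noise(100L, spec$noise_sd)
  v <- (v - min(v)) / (max(v) - min(v))
  list(breath = normalized_breath(v),
       label = factor(severity_label(spec), levels = ifl_classes()))
}

# Random family parameters for one stratified draw. Ranges are the
# generator's fixed study conditions (see the methods vignette).
random_spec <- function(class, noise_sd, include_inverted) {
  inv <- include_inverted && stats::runif(1) < 0.5
  switch(class,
    NIFL = breath_spec("sinusoidal", skew = stats::runif(1, 0.83, 0.89),
                       noise_sd = noise_sd, time_inverted = inv),
    IFL1 = if (stats::runif(1) < 0.5)
      breath_spec("mild_flat",
                  plateau_level = stats::runif(1, 0.72, 0.80),
                  plateau_width = stats::runif(1, 0.32, 0.40),
                  skew = stats::runif(1, 0.85, 0.95),
                  noise_sd = noise_sd, time_inverted = inv)
    else {
      # ripple prominence scales with peak count so 2- and 3-peak members
      # are comparably deformed
      np <- sample(2:3, 1L)
      breath_spec("multi_peak", n_peaks = np,
                  ripple_amp = if (np == 2L) stats::runif(1, 0.050, 0.062)
                               else stats::runif(1, 0.080, 0.100),
                  skew = stats::runif(1, 0.85, 0.95),
                  noise_sd = noise_sd, time_inverted = inv)
    },
    IFL2 = breath_spec("flat_top",
                       plateau_level = stats::runif(1, 0.50, 0.58),
                       plateau_width = stats::runif(1, 0.58, 0.78),
                       skew = stats::runif(1, 0.85, 0.95),
                       noise_sd = noise_sd, time_inverted = inv))
}

#' Generate a labelled synthetic breath dataset
#'
#' Stratified sample with `n_per_class` breaths per severity class.
#' Within-family parameters are randomised over the generator's fixed
#' ranges; the IFL1 class is an even mixture of mildly flattened and
#' multi-peak breaths; half of the breaths are time-inverted when
#' `include_inverted` is on. Fully reproducible for a given `seed`.
#'
#' @param n_per_class Breaths per class (>= 1).
#' @param noise_sd Noise standard deviation (fraction of peak). Default
#'   0.02.
#' @param seed Integer RNG seed (required, to make datasets reproducible).
#' @param include_inverted Also draw time-inverted variants. Default `TRUE`.
#' @return A list of class `breath_dataset` with `values` (matrix, one
#'   100-point breath per row), `labels` (factor) and `specs` (list of
#'   [breath_spec()]).
#' @export
generate_dataset <- function(n_per_class, noise_sd = 0.02, seed,
                             include_inverted = TRUE) {
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is required for dataset generation", call. = FALSE)
  set.seed(seed)
  classes <- rep(ifl_classes(), each = n_per_class)
  specs <- lapply(classes, random_spec, noise_sd = noise_sd,
                  include_inverted = include_inverted)
  vals <- t(vapply(specs, function(sp) generate_breath(sp)$breath$values,
                   numeric(100L)))
  structure(list(values = vals,
                 labels = factor(classes, levels = ifl_classes()),
                 specs = specs),
            class = "breath_dataset")
}

#' @export
print.breath_dataset <- function(x, ...) {
  cat(sprintf("<breath_dataset: %d breaths (%s)>\n", nrow(x$values),
              paste(sprintf("%s %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a breath dataset to CSV
#'
#' One row per breath: `label,v0,...,v99`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "breath_dataset"))
  df <- data.frame(label = as.character(dataset$labels), dataset$values)
  names(df) <- c("label", paste0("v", 0:99))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a breath dataset from CSV
#'
#' @param path CSV with columns `label,v0,...,v99` (label optional).
#' @return A `breath_dataset` (labels `NULL` when the column is absent).
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) != 100L)
    stop("dataset must contain columns v0..v99", call. = FALSE)
  vcols <- paste0("v", 0:99)
  labels <- if ("label" %in% names(df)) ifl_factor(df$label) else NULL
  structure(list(values = as.matrix(df[, vcols]), labels = labels,
                 specs = NULL),
            class = "breath_dataset")
}
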
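#' End-to-end IFL detection on a flow trace or pre-segmented breaths
#'
#' Runs the full chain: load (when `input` is a path), low-pass filter,
#' segment inspirations, normalize each breath, compute the five shape
#' features and classify every breath with the requested method. When
#' `input` is a `breath_dataset` (pre-segmented normalized breaths) the
#' filtering/segmentation stages are skipped.
#'
#' @param input A file path, [flow_signal()], or `breath_dataset`.
#' @param method Feature method used for labelling: one of `"fi"`,
#'   `"order1"`, `"order2"`, `"order3"`, `"w3"`. Default `"w3"`.
#' @param cutoffs A [cutoff_set()] for `method`, or a named list holding
#'   one; defaults to the shipped cut-offs.
#' @param sampling_rate Passed to [load_flow_signal()] for flow-only files.
#' @param filter_cutoff Low-pass cut-off in Hz. Default 2.
#' @param min_duration Minimum inspiration length in seconds. Default 0.5.
#' @param A,B,C Weight factors for the weighted third-order feature.
#' @return List with `breaths` (segment table or `NULL`), `features`
#'   (feature table) and `labels` (data frame `breath_id, method, score,
#'   label`).
#' @export
detect_ifl <- function(input, method = "w3", cutoffs = NULL,
                       sampling_rate = NULL, filter_cutoff = 2,
                       min_duration = 0.5, A = 50, B = 200, C = 1) {
  method <- match.arg(method, c("fi", "order1", "order2", "order3", "w3"))
  if (is.null(cutoffs)) cutoffs <- default_cutoffs(method)
  if (!inherits(cutoffs, "cutoff_set")) {
    if (!method %in% names(cutoffs))
      stop(sprintf("no cut-offs supplied for method '%s'", method),
           call. = FALSE)
    cutoffs <- cutoffs[[method]]
  }

  seg_table <- NULL
  if (inherits(input, "breath_dataset")) {
    normed <- lapply(seq_len(nrow(input$values)),
                     function(i) normalized_breath(input$values[i, ]))
  } else {
    sig <- if (inherits(input, "flow_signal")) input
           else load_flow_signal(input, sampling_rate = sampling_rate)
    sig <- lowpass_filter(sig, filter_cutoff)
    brs <- segment_inspirations(sig, min_duration)
    if (length(brs) == 0L)
      stop("no inspiratory breaths found in the input signal", call. = FALSE)
    seg_table <- breath_table(brs, sig$sampling_rate)
    normed <- lapply(brs, normalize_breath)
  }

  feats <- feature_table(normed, A = A, B = B, C = C)
  col <- c(fi = "fi", order1 = "r1", order2 = "r2", order3 = "r3",
           w3 = "rw3")[[method]]
  scores <- feats[[col]]
  labels <- classify_breath(scores, cutoffs)
  list(breaths = seg_table,
       features = feats,
       labels = data.frame(breath_id = feats$breath_id, method = method,
                           score = scores, label = as.character(labels)))
}
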
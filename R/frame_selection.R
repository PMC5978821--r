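#' Score every frame of a recording against its pixelwise median
#'
#' A deterministic surrogate for visually scanning a thermal video for the
#' best frames.  The reference image is the pixelwise median across all
#' frames — robust to a minority of motion-corrupted frames — and each
#' frame's quality score is its centred (Pearson) correlation with that
#' reference, so scores lie in `[-1, 1]` and a global temperature bias does
#' not mask a geometric disturbance.
#'
#' Conventions for degenerate cases: a single-frame recording scores 1; a
#' zero-variance (constant) frame, or any frame when the reference itself
#' has zero variance, scores 0.
#'
#' @param recording A [thermal_recording].
#' @return A data frame with one row per frame: `frame_index`, `score`.
#' @seealso [select_best_frames()]
#' @export
score_frames <- function(recording) {
  stopifnot(inherits(recording, "thermal_recording"))
  n <- n_frames(recording)
  if (n == 1L)
    return(data.frame(frame_index = 1L, score = 1))
  npx <- prod(frame_shape(recording))
  x <- vapply(recording$frames, function(f) as.vector(f$temps),
              numeric(npx))
  ref <- apply(x, 1L, median)
  ref_sd <- stats::sd(ref)
  score <- vapply(seq_len(n), function(i) {
    v <- x[, i]
    if (ref_sd == 0 || stats::sd(v) == 0) return(0)
    cor(v, ref)
  }, numeric(1))
  data.frame(frame_index = seq_len(n), score = score)
}

#' Select the k best frames of a recording
#'
#' Ranks frames by the [score_frames()] quality score and returns the `k`
#' highest-scoring frame indices (ties broken towards the earlier frame),
#' sorted ascending.  The study protocol keeps the 20 best of 600; `k` is
#' configurable for simulation work.  If the recording holds fewer than `k`
#' frames, all indices are returned with a warning.  One selection is made
#' per recording and shared by all ROIs measured on it.
#'
#' @param recording A [thermal_recording].
#' @param k Number of frames to keep (>= 1); default 20.
#' @return Integer vector of selected 1-based frame indices, ascending.
#' @export
select_best_frames <- function(recording, k = 20L) {
  stopifnot(inherits(recording, "thermal_recording"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_tl("`k` must be >= 1")
  sc <- score_frames(recording)
  n <- nrow(sc)
  if (n < k) {
    warning(sprintf("recording has only %d frames; keeping all (k = %d)", n, k),
            call. = FALSE)
    return(sc$frame_index)
  }
  ord <- order(-sc$score, sc$frame_index)
  sort(sc$frame_index[ord[seq_len(k)]])
}
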
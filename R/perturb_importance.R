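#' Perturbation-importance configuration
#'
#' @param n_iterations number of sampled ROI subsets (default 10,000).
#' @param k subset size, ROIs zeroed together (default 12; covers multi-ROI
#'   interactions at reasonable cost).
#' @param batch_size validation batch size (default 64).
#' @param seed integer seed.
#' @return object of class `perturbation_config`.
#' @export
perturbation_config <- function(n_iterations = 10000L, k = 12L,
                                batch_size = 64L, seed = 1L) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (k < 1L) stop("k must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations), k = as.integer(k),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Zero out a subset of ROIs in a sample batch
#'
#' Sets the selected ROI rows to 0 across all time points of every sample,
#' making those features unusable by any model; all other entries are
#' untouched and the input is not modified in place. Zeroing acts on the
#' model's input representation (after any standardization the pipeline
#' applied upstream).
#'
#' @param batch `n x rois x t` sample array.
#' @param rois non-empty vector of 1-based ROI indices.
#' @return perturbed copy of `batch`.
#' @export
zero_perturbation <- function(batch, rois) {
  if (length(rois) == 0) stop("ROI subset must be non-empty")
  d <- dim(batch)
  if (any(rois < 1L | rois > d[2])) stop("ROI index out of range")
  out <- batch
  out[, rois, ] <- 0
  out
}

#' Fraction of predictions flipped by a perturbation
#'
#' Compares hard class predictions of a model on an original and a perturbed
#' batch: `s = mean(p != p_perturbed)`, in \[0, 1\].
#'
#' @param model any model accepted by [predict_labels()].
#' @param batch,perturbed sample arrays of identical shape.
#' @return flip fraction.
#' @export
prediction_flip_score <- function(model, batch, perturbed) {
  if (!identical(dim(batch), dim(perturbed))) stop("batch size/shape mismatch")
  mean(predict_labels(model, batch) != predict_labels(model, perturbed))
}

#' Subset-zeroing perturbation importance
#'
#' For each of `n_iterations` iterations, samples one uniform k-subset of
#' ROIs (reused across all validation batches of that iteration), zeroes it
#' in every batch, and records the batch's prediction-flip fraction in the
#' buffer of every ROI in the subset. The mean of each ROI's buffer is its
#' importance: ROIs whose removal frequently changes the model's decisions
#' score high. Applicable to any fitted model, including black-box neural
#' networks.
#'
#' @param model any model accepted by [predict_labels()].
#' @param validation an `rd_dataset` used as the perturbation corpus.
#' @param config a [perturbation_config()].
#' @return object of class `perturbation_scores`: `mean_scores` (named by
#'   ROI index), `n_observations` per ROI, and the raw `buffers`.
#' @export
perturbation_importance <- function(model, validation, config = perturbation_config()) {
  stopifnot(inherits(validation, "rd_dataset"),
            inherits(config, "perturbation_config"))
  n <- dim(validation$x)[1]
  n_rois <- dim(validation$x)[2]
  if (n == 0) stop("validation set is empty")
  if (config$k > n_rois) stop("k exceeds the number of ROIs")
  batch_starts <- seq(1L, n, by = config$batch_size)
  batches <- lapply(batch_starts, function(s) s:min(s + config$batch_size - 1L, n))
  orig_pred <- predict_labels(model, validation$x)
  buffers <- rep(list(numeric(0)), n_rois)
  set.seed(config$seed)
  for (i in seq_len(config$n_iterations)) {
    rois <- sample.int(n_rois, config$k)
    # the subset is shared by every batch of this iteration, so one forward
    # pass over the whole perturbed validation set scores all batches
    pred <- predict_labels(model, zero_perturbation(validation$x, rois))
    for (idx in batches) {
      s <- mean(pred[idx] != orig_pred[idx])
      for (r in rois) buffers[[r]] <- c(buffers[[r]], s)
    }
  }
  n_obs <- lengths(buffers)
  mean_scores <- vapply(buffers, function(b) if (length(b)) mean(b) else NA_real_,
                        numeric(1))
  names(mean_scores) <- names(n_obs) <- as.character(seq_len(n_rois))
  structure(list(mean_scores = mean_scores, n_observations = n_obs,
                 buffers = buffers, config = config),
            class = "perturbation_scores")
}

#' @export
print.perturbation_scores <- function(x, ...) {
  cat(sprintf("<perturbation_scores> %d ROIs, N = %d iterations, k = %d\n",
              length(x$mean_scores), x$config$n_iterations, x$config$k))
  top <- order(x$mean_scores, decreasing = TRUE)[seq_len(min(5, length(x$mean_scores)))]
  cat("top ROIs:", paste(sprintf("%s (%.3f)", names(x$mean_scores)[top],
                                 x$mean_scores[top]), collapse = ", "), "\n")
  invisible(x)
}
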
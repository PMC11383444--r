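#' @export
#' @method print maskgnn
print.maskgnn <- function(x, ...) {
  cat("Masked graph neural network fit\n")
  cat(sprintf("  task: %s   modalities: %s   Q = %d ROIs\n",
              x$task, paste(x$config$modalities, collapse = "+"),
              nrow(x$mask)))
  cat(sprintf("  epochs run: %d   final lr: %.4g\n",
              nrow(x$history), x$history$lr[nrow(x$history)]))
  if (x$task == "regression") {
    cat(sprintf("  test RMSE %.4f   test MAE %.4f\n",
                x$metrics$rmse, x$metrics$mae))
  } else {
    cat(sprintf("  test accuracy %.3f   F1 %.3f   AUC %.3f\n",
                x$metrics$accuracy, x$metrics$f1, x$metrics$auc))
  }
  invisible(x)
}

#' @export
#' @method summary maskgnn
summary.maskgnn <- function(object, ...) {
  m <- object$mask
  off <- m[upper.tri(m)]
  tm <- threshold_mask(m, object$config$vis_threshold)
  cat("Masked graph neural network fit\n\n")
  print(object)
  cat(sprintf("\nLearned mask (off-diagonal): min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  cat(sprintf("Edges above visualization threshold %.2f: %d of %d pairs\n",
              object$config$vis_threshold, tm$n_edges, length(off)))
  if (length(object$events) > 0) {
    cat("\nTraining events:\n")
    for (e in object$events) cat("  -", e, "\n")
  }
  invisible(list(mask_summary = summary(off), thresholded = tm))
}

#' Extract fitted parameters
#'
#' By default returns the learned edge mask `M = sigmoid(V + V^T)` — the
#' model's interpretable coefficient object. `which = "all"` returns the
#' full parameter list.
#'
#' @param object A `maskgnn` fit.
#' @param which `"mask"` (default) or `"all"`.
#' @param ... Unused.
#' @export
coef.maskgnn <- function(object, which = c("mask", "all"), ...) {
  which <- match.arg(which)
  if (which == "mask") object$mask else object$state[param_names]
}

#' Predict from a fitted masked GNN
#'
#' @param object A `maskgnn` fit.
#' @param cohort A `maskgnn_cohort` with the subjects to predict.
#' @param ids Subject ids (default: all subjects usable under the fit's
#'   task).
#' @param type `"response"` (regression values / class labels) or
#'   `"score"` (raw outputs; logits for classification).
#' @param ... Unused.
#' @return Matrix of predictions (rownames = subject ids), or an integer
#'   label vector for classification with `type = "response"`.
#' @export
predict.maskgnn <- function(object, cohort, ids = NULL,
                            type = c("response", "score"), ...) {
  type <- match.arg(type)
  data <- prepare_graphs(cohort, object$config)
  if (is.null(ids)) ids <- data$ids
  idx <- match(ids, data$ids)
  if (anyNA(idx)) stop("predict.maskgnn: unknown subject ids")
  preds <- predict_indices(object$state, data, idx)
  rownames(preds) <- ids
  if (object$task == "classification" && type == "response") {
    stats::setNames(ifelse(preds[, 2] > preds[, 1], 2L, 1L), ids)
  } else {
    preds
  }
}

#' @export
residuals.maskgnn <- function(object, cohort = NULL, ...) {
  if (is.null(cohort))
    stop("residuals.maskgnn: supply the cohort the model was fitted on")
  if (object$task != "regression")
    stop("residuals.maskgnn: residuals are defined for regression fits")
  data <- prepare_graphs(cohort, object$config)
  idx <- match(object$test_ids, data$ids)
  data$y[idx, , drop = FALSE] - object$predictions
}

#' Plot a fitted mask or the training history
#'
#' @param x A `maskgnn` fit.
#' @param what `"mask"` (heatmap of the learned edge mask) or `"history"`
#'   (loss curves).
#' @param ... Passed to [graphics::image()] / [graphics::matplot()].
#' @export
plot.maskgnn <- function(x, what = c("mask", "history"), ...) {
  what <- match.arg(what)
  if (what == "mask") {
    m <- x$mask
    diag(m) <- NA
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    xlab = "ROI", ylab = "ROI",
                    main = "Learned edge mask", ...)
  } else {
    h <- x$history
    graphics::matplot(h$epoch, cbind(h$train_e, h$val_e), type = "l",
                      lty = 1, col = c("black", "red"),
                      xlab = "epoch", ylab = "prediction loss", ...)
    graphics::legend("topright", c("train", "validation"),
                     lty = 1, col = c("black", "red"), bty = "n")
  }
  invisible(x)
}

#' Simulate a cohort from a fitted model's configuration
#'
#' Convenience wrapper: draws `nsim` synthetic cohorts matching the fit's
#' parcellation size, using [generate_cohort()].
#'
#' @param object A `maskgnn` fit.
#' @param nsim Number of cohorts.
#' @param seed Seed for the generator.
#' @param ... Overrides passed to [synthetic_spec()].
#' @export
simulate.maskgnn <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$config$seed
  out <- lapply(seq_len(nsim), function(i) {
    sp <- synthetic_spec(q = object$state$dims$q, seed = seed + i - 1, ...)
    generate_cohort(sp)
  })
  if (nsim == 1) out[[1]] else out
}
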
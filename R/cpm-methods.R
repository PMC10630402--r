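#' @export
#' @method print cpm
print.cpm <- function(x, ...) {
  cfg <- x$config
  cat("Connectome-based predictive model\n")
  cat(sprintf("  %d subjects, %d edges%s\n", x$n_subjects, x$n_edges,
              if (cfg$masked) sprintf(" (selection restricted to %d)",
                                      cfg$n_candidates) else ""))
  cat(sprintf("  %d-fold CV x %d iterations, |r| > %.2g selection, %s model\n",
              cfg$k_folds, cfg$n_iterations, cfg$threshold, cfg$model))
  cat(sprintf("  median Spearman accuracy: %.3f\n", x$median_accuracy))
  invisible(x)
}

#' @export
#' @method summary cpm
summary.cpm <- function(object, robust_fraction = 0.97, ...) {
  rb <- robust_edges(object, fraction = robust_fraction)
  out <- list(median_accuracy = object$median_accuracy,
              accuracy_quantiles = stats::quantile(
                object$accuracies, c(0.025, 0.25, 0.5, 0.75, 0.975)),
              n_iterations = object$config$n_iterations,
              robust_fraction = robust_fraction,
              n_robust_positive = length(rb$positive),
              n_robust_negative = length(rb$negative),
              final_coef = coef(object),
              config = object$config)
  class(out) <- "summary.cpm"
  out
}

#' @export
#' @method print summary.cpm
print.summary.cpm <- function(x, ...) {
  cat("CPM summary\n")
  cat(sprintf("  median accuracy %.3f over %d iterations\n",
              x$median_accuracy, x$n_iterations))
  cat("  accuracy quantiles:\n")
  print(round(x$accuracy_quantiles, 3))
  cat(sprintf("  robust edges (>= %.0f%% of models): %d positive, %d negative\n",
              100 * x$robust_fraction, x$n_robust_positive,
              x$n_robust_negative))
  cat("  full-sample strength-model coefficients:\n")
  print(round(x$final_coef, 4))
  invisible(x)
}

#' Coefficients of the full-sample network-strength model
#'
#' @param object a fitted [cpm()] object.
#' @param ... unused.
#' @return named coefficient vector (combined mode) or list of per-tail
#'   coefficient vectors.
#' @export
coef.cpm <- function(object, ...) {
  m <- object$final$model
  if (m$mode == "combined") m$coefficients
  else list(positive = m$positive, negative = m$negative)
}

#' Predict behavior for new subjects from a fitted CPM
#'
#' Applies the full-sample edge mask and network-strength model to new
#' subjects' edge vectors. Predictions are on the residualized-target scale;
#' if the model used confounds, supply the new subjects' confounds so their
#' observed targets can be residualized the same way before comparison.
#'
#' @param object a fitted [cpm()] object.
#' @param newdata subjects x edges matrix (same edge convention and count).
#' @param ... unused.
#' @return numeric predicted (residualized) behavior.
#' @export
predict.cpm <- function(object, newdata, ...) {
  newdata <- if (inherits(newdata, "subject_dataset")) newdata$edges
             else as.matrix(newdata)
  if (ncol(newdata) != object$n_edges)
    stop("newdata must have ", object$n_edges, " edge columns")
  s <- network_strength(newdata, object$final$mask)
  p <- predict(object$final$model, s)
  if (object$config$model == "separate_tails") p <- rowMeans(p)
  p
}

#' @export
residuals.cpm <- function(object, ...) {
  apply(object$observed - object$predictions, 1L, stats::median)
}

#' Plot the cross-validation accuracy distribution of a CPM
#'
#' Boxplot of per-iteration Spearman accuracies with the median marked;
#' when a [permutation_test()] result is supplied its null distribution is
#' drawn alongside, mirroring the usual true-vs-null display.
#'
#' @param x a fitted [cpm()] object.
#' @param permtest optional `cpm_permtest` for the same model.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.cpm <- function(x, permtest = NULL, ...) {
  if (is.null(permtest)) {
    graphics::boxplot(x$accuracies, ylab = "Spearman accuracy",
                      names = "true", ...)
  } else {
    graphics::boxplot(list(true = x$accuracies,
                           null = permtest$null_accuracies),
                      ylab = "Spearman accuracy", ...)
  }
  graphics::abline(h = x$median_accuracy, lty = 2)
  invisible(x)
}
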
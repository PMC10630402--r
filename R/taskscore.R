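#' Score one-back trials into hits and false alarms
#'
#' In the one-back matching task each image is judged "same" or "different"
#' relative to the immediately preceding image. A hit is a "same" response
#' when the correct answer is same; a false alarm is a "same" response when
#' the correct answer is different. The first image of each block has no
#' predecessor and is never scored. A missing response (`"none"` or NA) is
#' treated as "different": under these definitions a non-"same" response can
#' neither hit nor false-alarm.
#'
#' @param trials data.frame with columns `block` (integer), `condition`
#'   (e.g. "attend_faces"/"attend_houses"), `truth` ("same"/"different", NA
#'   for the unscorable first image of a block) and `response` ("same",
#'   "different" or "none"/NA). Typically from [simulate_task_trials()] or
#'   [read_trials()].
#' @param condition which condition to score.
#' @param dprime if TRUE (default) also compute log-linear-corrected d-prime
#'   via [dprime_loglinear()].
#' @return list of class `oneback_counts` with `hits`, `false_alarms`,
#'   `n_signal`, `n_noise`, `condition` and (optionally) `d_prime`.
#' @export
score_oneback <- function(trials, condition, dprime = TRUE) {
  req <- c("block", "condition", "truth", "response")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials is missing column(s): ",
                         paste(miss, collapse = ", "))
  avail <- unique(trials$condition)
  if (!condition %in% avail)
    stop("condition '", condition, "' not present; available: ",
         paste(avail, collapse = ", "))
  tr <- trials[trials$condition == condition & !is.na(trials$truth), ,
               drop = FALSE]
  said_same <- !is.na(tr$response) & tr$response == "same"
  is_signal <- tr$truth == "same"
  out <- list(hits = sum(said_same & is_signal),
              false_alarms = sum(said_same & !is_signal),
              n_signal = sum(is_signal),
              n_noise = sum(!is_signal),
              condition = condition)
  if (dprime)
    out$d_prime <- dprime_loglinear(out$hits, out$false_alarms,
                                    out$n_signal, out$n_noise)
  class(out) <- "oneback_counts"
  out
}

#' @export
#' @method print oneback_counts
print.oneback_counts <- function(x, ...) {
  cat("One-back performance (", x$condition, ")\n", sep = "")
  cat(sprintf("  hits: %d / %d   false alarms: %d / %d\n",
              x$hits, x$n_signal, x$false_alarms, x$n_noise))
  if (!is.null(x$d_prime))
    cat(sprintf("  d' (log-linear corrected): %.4f\n", x$d_prime))
  invisible(x)
}

#' Log-linear-corrected d-prime
#'
#' Signal-detection sensitivity d' = z(hit rate) - z(false alarm rate),
#' with the log-linear correction applied unconditionally: 0.5 is added to
#' both the hit and false-alarm counts and 1 to both the signal and noise
#' trial counts, so the z-transform is always finite even at perfect or
#' zero proportions:
#'
#'   d' = qnorm((hits + 0.5) / (n_signal + 1)) -
#'        qnorm((false_alarms + 0.5) / (n_noise + 1))
#'
#' @param hits,false_alarms,n_signal,n_noise trial counts; vectors recycle.
#' @return numeric d-prime, always finite.
#' @examples
#' dprime_loglinear(27, 0, 27, 33)  # perfect hits, no false alarms
#' @export
dprime_loglinear <- function(hits, false_alarms, n_signal, n_noise) {
  if (any(n_signal < 1) || any(n_noise < 1))
    stop("n_signal and n_noise must be >= 1")
  if (any(hits < 0) || any(hits > n_signal))
    stop("hits must lie in [0, n_signal]")
  if (any(false_alarms < 0) || any(false_alarms > n_noise))
    stop("false_alarms must lie in [0, n_noise]")
  stats::qnorm((hits + 0.5) / (n_signal + 1)) -
    stats::qnorm((false_alarms + 0.5) / (n_noise + 1))
}
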
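# Kaplan-Meier survival probability at a single time point.
# Product-limit over event times <= t; censoring handled by the risk set.
.km_at <- function(time, event, t) {
  if (!length(time)) return(NA_real_)
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event == 1 & time <= t])
  s <- 1
  for (tt in ut) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

#' Time-dependent ROC curve by the Kaplan-Meier method
#'
#' Estimates sensitivity and specificity for predicting event status by a
#' fixed horizon t from a continuous marker, with censoring handled by the
#' Kaplan-Meier estimator (the cumulative/dynamic KM form): for a threshold
#' c,
#' \deqn{sens(c,t) = (1 - S(t | X > c)) P(X > c) / (1 - S(t)),}
#' \deqn{spec(c,t) = S(t | X \le c) P(X \le c) / S(t),}
#' with all survival functions estimated by Kaplan-Meier. With no censoring
#' before t this reduces exactly to the empirical binary ROC for the outcome
#' "event by t". The AUC is the trapezoidal integral over the curve.
#'
#' @param scores named numeric marker vector (higher = higher risk).
#' @param surv survival table aligned by \code{sample_id}.
#' @param horizon evaluation time t; must not exceed the largest observed
#'   time, and at least one event must occur at or before t.
#' @return An object of class \code{roc_curve}: list with \code{horizon},
#'   \code{thresholds} (ascending, first is -Inf), \code{sens},
#'   \code{spec}, \code{auc}, \code{n}, \code{n_events}.
#' @export
time_dependent_roc <- function(scores, surv, horizon) {
  surv <- validate_survival(surv)
  if (!is.null(names(scores))) scores <- scores[surv$sample_id]
  if (length(scores) != nrow(surv)) stop("scores/survival length mismatch")
  time <- surv$time; event <- surv$event
  if (horizon > max(time)) stop("horizon beyond observed follow-up")
  if (sum(event == 1 & time <= horizon) < 1L) stop("no events before horizon")
  s_all <- .km_at(time, event, horizon)
  thresholds <- c(-Inf, sort(unique(scores)))
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    hi <- scores > thresholds[i]
    p_hi <- mean(hi)
    s_hi <- if (any(hi)) .km_at(time[hi], event[hi], horizon) else 1
    s_lo <- if (any(!hi)) .km_at(time[!hi], event[!hi], horizon) else 1
    sens[i] <- if (s_all < 1) (1 - s_hi) * p_hi / (1 - s_all) else 0
    spec[i] <- if (s_all > 0) s_lo * (1 - p_hi) / s_all else 0
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  fpr <- 1 - spec
  # thresholds ascend, so fpr descends 1 -> 0; trapezoid in that order
  auc <- sum(diff(-fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(horizon = horizon, thresholds = thresholds,
                 sens = sens, spec = spec, auc = auc,
                 n = length(scores),
                 n_events = sum(event == 1 & time <= horizon)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: horizon %g, AUC %.4f (%d samples, %d events by t)\n",
              x$horizon, x$auc, x$n, x$n_events))
  invisible(x)
}

#' Youden-optimal cutoff from a time-dependent ROC curve
#'
#' Returns the finite threshold maximizing sensitivity + specificity;
#' ties are broken toward the smallest threshold.
#'
#' @param roc a \code{roc_curve}.
#' @return Numeric cutoff (one of the observed marker values).
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  finite <- is.finite(roc$thresholds)
  if (!any(finite)) stop("no finite thresholds on the curve")
  youden <- (roc$sens + roc$spec)[finite]
  th <- roc$thresholds[finite]
  # thresholds ascend: the first value within numerical round-off of the
  # maximum is the smallest maximizing threshold
  th[which(youden >= max(youden) - 1e-9)[1]]
}

#' Write an ROC curve as TSV
#' @param roc a \code{roc_curve}.
#' @param path file path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(
    data.frame(threshold = roc$thresholds, sensitivity = roc$sens,
               specificity = roc$spec),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
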
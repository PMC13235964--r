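## Markov-blanket survival prediction: Cox models restricted to the Markov
## blanket of a censored outcome in a learned graph, evaluated by Harrell's
## concordance (optionally horizon-truncated) under cross-validation.

## Encode a feature list (MB members) into a numeric design matrix:
## continuous pass through, discrete are reference-encoded, censored
## features enter as their null-model Martingale residuals.
encode_features <- function(data, features) {
  if (!length(features)) return(matrix(0, data$n, 0))
  expand_conditioning_set(features, data)
}

#' Fit a Cox model on the Markov blanket of a censored outcome
#'
#' Extracts `markov_blanket(graph, target)`, encodes the blanket features,
#' and fits a proportional hazards model (Efron ties, Newton-Raphson) with
#' per-feature hazard ratios and Wald confidence intervals. An empty
#' blanket yields the null model with a warning.
#'
#' @param data A `mixed_dataset`.
#' @param graph A learned `endpoint_graph` (cpdag/pag/dag).
#' @param target Name of a censored variable.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @return An object of class `"mb_cox"`: `target`, `mb`, `fit`,
#'   `coef_table`, `basehaz`, `feature_names`.
#' @export
fit_mb_cox <- function(data, graph, target, conf_level = 0.95) {
  if (var_kind(data, target) != "censored") stop("target must be censored")
  if (sum(data$event[, target]) < 1) stop("target has zero observed events")
  mb <- markov_blanket(graph, target)
  if (!length(mb)) warning("empty Markov blanket for ", target,
                           "; fitting null model")
  X <- encode_features(data, mb)
  fit <- cox_fit(X, data$time[, target], data$event[, target])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coef_table <- if (length(fit$coef)) data.frame(
    feature = colnames(X),
    coef = fit$coef, se = fit$se,
    hr = exp(fit$coef),
    hr_lo = exp(fit$coef - z * fit$se),
    hr_hi = exp(fit$coef + z * fit$se),
    row.names = NULL
  ) else data.frame(feature = character(0), coef = numeric(0), se = numeric(0),
                    hr = numeric(0), hr_lo = numeric(0), hr_hi = numeric(0))
  eta <- if (ncol(X)) drop(X %*% fit$coef) else rep(0, data$n)
  structure(list(target = target, mb = mb, fit = fit,
                 coef_table = coef_table,
                 basehaz = breslow_cumhaz(data$time[, target],
                                          data$event[, target], eta),
                 feature_names = colnames(X)),
            class = "mb_cox")
}

#' @export
print.mb_cox <- function(x, ...) {
  cat("Markov-blanket Cox predictor for", x$target, "\n")
  cat("  blanket:", if (length(x$mb)) paste(x$mb, collapse = ", ") else "(empty)", "\n")
  if (nrow(x$coef_table)) print(x$coef_table, digits = 3)
  invisible(x)
}

#' Linear risk score of a Markov-blanket Cox predictor
#'
#' Higher scores mean higher hazard.
#'
#' @param predictor An `"mb_cox"` object.
#' @param new_data A `mixed_dataset` containing all blanket features.
#' @return Numeric vector of length `new_data$n`.
#' @export
risk_score <- function(predictor, new_data) {
  missing_f <- setdiff(predictor$mb, dataset_var_names(new_data))
  if (length(missing_f))
    stop("missing MB feature(s) in new data: ", paste(missing_f, collapse = ", "))
  X <- encode_features(new_data, predictor$mb)
  if (!ncol(X)) return(rep(0, new_data$n))
  drop(X[, predictor$feature_names, drop = FALSE] %*% predictor$fit$coef)
}

#' Harrell's concordance index
#'
#' Over comparable pairs (the earlier time is an observed event and the
#' times differ), the fraction where the earlier event carries the higher
#' risk score; score ties count one half. With a horizon `tau`, pairs whose
#' earlier time exceeds `tau` are excluded.
#'
#' @param scores Risk scores (higher = higher hazard).
#' @param time,status Survival outcome.
#' @param tau Optional time horizon.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_concordance <- function(scores, time, status, tau = NULL) {
  stopifnot(length(scores) == length(time), length(time) == length(status))
  n <- length(time)
  conc <- comp <- 0
  for (i in seq_len(n)) {
    if (status[i] != 1) next
    if (!is.null(tau) && time[i] > tau) next
    later <- which(time > time[i])
    if (!length(later)) next
    comp <- comp + length(later)
    conc <- conc + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

#' Cross-validated concordance of a graph-driven MB predictor
#'
#' Per fold: learns a graph and the MB predictor on the training split,
#' scores the held-out split; pools the held-out scores and computes
#' Harrell's concordance. Folds with zero training or test events are
#' skipped with a warning. Deterministic given `seed`.
#'
#' @param data A `mixed_dataset`.
#' @param graph_learner Function `(train_data) -> endpoint_graph`.
#' @param target Censored outcome name.
#' @param folds Number of folds (default 10).
#' @param seed Seed driving the fold assignment.
#' @param tau Optional concordance horizon.
#' @return List with `concordance`, `fold` assignment, per-fold `models`,
#'   pooled `scores`.
#' @export
cross_validated_concordance <- function(data, graph_learner, target,
                                        folds = 10L, seed = 1L, tau = NULL) {
  stopifnot(folds >= 2L)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), data$n))
  scores <- rep(NA_real_, data$n)
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (sum(data$event[tr, target]) < 1) {
      warning("fold ", f, " has zero training events; skipped")
      next
    }
    dtr <- dataset_subset(data, tr)
    dte <- dataset_subset(data, te)
    g <- graph_learner(dtr)
    pred <- fit_mb_cox(dtr, g, target)
    models[[f]] <- pred
    scores[te] <- risk_score(pred, dte)
  }
  ok <- !is.na(scores)
  cidx <- harrell_concordance(scores[ok], data$time[ok, target],
                              data$event[ok, target], tau = tau)
  list(concordance = cidx, fold = fold, models = models, scores = scores)
}
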
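## Stability-based penalty selection for CoxMGM.
##
## StARS selects the smallest penalty whose edge set stays reproducible
## across subsamples; StEPS applies the same rule separately per edge type
## (cc, cd, dd, sc, sd), reading each type's instability curve off a shared
## penalty path.

#' Build a decreasing log-spaced penalty path
#'
#' The path starts at `lambda_max`, the smallest penalty that yields an
#' empty graph (found by doubling search and bisection refinement), and
#' descends log-evenly to `lambda_max / 100`.
#'
#' @param data A `mixed_dataset`.
#' @param K Number of path points (>= 2).
#' @param ... Passed to [fit_coxmgm()] (e.g. `tol`).
#' @return Numeric vector of K strictly decreasing penalties.
#' @export
build_lambda_path <- function(data, K = 30L, ...) {
  stopifnot(K >= 2L)
  empty_at <- function(lam) {
    fit <- fit_coxmgm(data, lam, max_iter = 200L, ...)
    n_edges(params_to_graph(fit)) == 0L
  }
  ## start the doubling search at the stationarity (KKT) bound: the largest
  ## penalized-group gradient norm at the intercepts-only solution, at and
  ## above which the all-zero interaction set is optimal
  lam <- max(kkt_lambda_bound(data), 1e-3)
  it <- 0L
  while (!empty_at(lam)) {
    lam <- lam * 2
    it <- it + 1L
    if (it > 40L) stop("lambda_max search did not converge")
  }
  lo <- lam / 2; hi <- lam
  for (i in 1:4) {                     # refine so the head of the path is tight
    mid <- sqrt(lo * hi)
    if (empty_at(mid)) hi <- mid else lo <- mid
  }
  hi <- hi * 1.1                       # margin: head stays empty on subsamples
  exp(seq(log(hi), log(hi / 100), length.out = K))
}

## Largest penalized-group gradient norm of the smooth loss at the
## intercepts-only parameter set.
kkt_lambda_bound <- function(data) {
  frame <- mgm_frame(data, standardize = TRUE)
  dims <- mgm_dims(data)
  params <- mgm_params_zero(dims)
  ## closed-form intercepts: standardized continuous means are 0; discrete
  ## intercepts are log observed level frequencies
  for (j in seq_len(dims$q)) {
    ph <- colMeans(frame$D[[j]])
    params$disc_int[[j]] <- log(pmax(ph, 1e-12))
  }
  g <- mgm_smooth(params, frame, gradient = TRUE)$grad
  mx <- 0
  p <- dims$p; q <- dims$q; r <- dims$r
  if (p > 1) mx <- max(mx, max(abs(g$beta[upper.tri(g$beta)])))
  for (j in seq_len(q)) {
    if (p > 0) mx <- max(mx, max(sqrt(rowSums(g$rho[[j]]^2))))
    if (r > 0) mx <- max(mx, max(sqrt(colSums(g$psi[[j]]^2))))
    if (j < q) for (k in (j + 1L):q)
      mx <- max(mx, sqrt(sum(g$phi[[j]][[k]]^2)))
  }
  if (p > 0 && r > 0) mx <- max(mx, max(abs(g$gamma)))
  mx
}

## Possible-edge counts per type, used to average instabilities.
edge_type_counts <- function(p, q, r) {
  c(cc = p * (p - 1) / 2, cd = p * q, dd = q * (q - 1) / 2,
    sc = p * r, sd = q * r)
}

## Per-pair edge-type labels aligned with an upper-triangular selection
## indicator over variables ordered (continuous, discrete, censored).
pair_types <- function(p, q, r) {
  kinds <- c(rep("c", p), rep("d", q), rep("s", r))
  N <- p + q + r
  out <- character(0)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    k <- paste0(sort(c(kinds[i], kinds[j])), collapse = "")
    out <- c(out, switch(k, cc = "cc", cd = "cd", dd = "dd",
                         cs = "sc", ds = "sd", ss = "ss"))
  }
  out
}

## Upper-triangular adjacency indicator of a skeleton graph.
adj_indicator <- function(g) {
  A <- g$marks != ""
  A[upper.tri(A)]
}

#' Edge-instability profile over a penalty path
#'
#' Fits CoxMGM on `B` subsamples (without replacement, size `b`) at every
#' path point and records, per edge type, the mean instability
#' `2 * theta * (1 - theta)` over possible edges of that type, where `theta`
#' is the per-edge selection frequency. Deterministic given `seed`
#' (per-subsample seeds are derived by index, so results do not depend on
#' evaluation order).
#'
#' @param data A `mixed_dataset`.
#' @param path Decreasing penalty path from [build_lambda_path()].
#' @param B Number of subsamples (default 20).
#' @param b Subsample size; default `min(floor(10*sqrt(n)), floor(0.75*n))`.
#' @param seed Master seed.
#' @param ... Passed to [fit_coxmgm()].
#' @return An object of class `"stability_profile"`: `path`, `instability`
#'   (K x 5 matrix, columns cc/cd/dd/sc/sd), `pooled` (length K), `B`, `b`,
#'   `seed`, `freq` (list of per-path-point selection frequencies).
#' @export
stability_profile <- function(data, path, B = 20L, b = NULL, seed = 1L, ...) {
  stopifnot(all(diff(path) < 0))
  n <- data$n
  if (is.null(b)) b <- min(floor(10 * sqrt(n)), floor(0.75 * n))
  if (b >= n) stop("subsample size b must be smaller than n")
  p <- data$p; q <- data$q; r <- data$r
  ptypes <- pair_types(p, q, r)
  K <- length(path)
  counts <- matrix(0, K, length(ptypes))

  for (bi in seq_len(B)) {
    set.seed(seed * 10000L + bi)
    idx <- NULL
    for (try in 1:10) {
      cand <- sample.int(n, b)
      ok <- r == 0 || all(colSums(data$event[cand, , drop = FALSE]) >= 1)
      if (ok) { idx <- cand; break }
      message("stability_profile: resampling subsample ", bi,
              " (zero events for a censored node)")
    }
    if (is.null(idx)) stop("subsample with zero events after 10 retries")
    sub <- dataset_subset(data, idx)
    init <- NULL
    for (k in seq_len(K)) {
      fit <- fit_coxmgm(sub, path[k], init = init, ...)
      init <- fit$params
      counts[k, ] <- counts[k, ] + adj_indicator(params_to_graph(fit))
    }
  }
  freq <- counts / B
  inst2 <- 2 * freq * (1 - freq)
  types <- c("cc", "cd", "dd", "sc", "sd")
  instability <- sapply(types, function(ty) {
    cols <- ptypes == ty
    if (!any(cols)) rep(NA_real_, K) else rowMeans(inst2[, cols, drop = FALSE])
  })
  instability <- matrix(instability, K, 5L, dimnames = list(NULL, types))
  pooled <- rowMeans(inst2)
  structure(list(path = path, instability = instability, pooled = pooled,
                 B = B, b = b, seed = seed, freq = freq, ptypes = ptypes),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("stability_profile: K =", length(x$path), "B =", x$B, "b =", x$b, "\n")
  df <- data.frame(lambda = signif(x$path, 4), round(x$instability, 4),
                   pooled = round(x$pooled, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

## Monotonize an instability curve: running maximum in the direction of
## decreasing lambda (path is stored decreasing, so plain cummax).
monotonize <- function(v) cummax(ifelse(is.na(v), 0, v))

select_from_curve <- function(path, curve, threshold) {
  mon <- monotonize(curve)
  ok <- which(mon <= threshold)
  if (!length(ok)) {
    warning("no path point satisfies the stability threshold; using largest lambda")
    return(path[1L])
  }
  path[max(ok)]                        # smallest lambda still under threshold
}

#' StEPS: per-edge-type stability selection
#'
#' For each edge type independently, monotonizes its instability curve
#' (running maximum as lambda decreases) and selects the smallest lambda
#' whose monotonized instability stays at or below `threshold`.
#'
#' @param profile A [stability_profile()].
#' @param threshold Instability threshold in (0, 0.5); default 0.05.
#' @return A [penalty_vector()] with the five selections. Types with no
#'   possible edges inherit the pooled (StARS) selection.
#' @export
steps_select <- function(profile, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 0.5)
  pooled_lam <- select_from_curve(profile$path, profile$pooled, threshold)
  out <- vapply(c("cc", "cd", "dd", "sc", "sd"), function(ty) {
    v <- profile$instability[, ty]
    if (all(is.na(v))) pooled_lam
    else select_from_curve(profile$path, v, threshold)
  }, 0)
  penalty_vector(out)
}

#' StARS: pooled stability selection
#'
#' As [steps_select()] but pooling the instability over all possible edges
#' into a single curve; the one selected lambda is broadcast to all five
#' edge types.
#'
#' @inheritParams steps_select
#' @return A [penalty_vector()] with five equal entries.
#' @export
stars_select <- function(profile, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 0.5)
  lam <- select_from_curve(profile$path, profile$pooled, threshold)
  penalty_vector(lam)
}

#' BIC score of a fitted CoxMGM
#'
#' `2 * negative_log_pseudolikelihood + log(n) * df` with `df` the number of
#' free nonzero parameters (interaction blocks by support, plus unpenalized
#' intercepts).
#'
#' @param data A `mixed_dataset`.
#' @param params An `mgm_params` list (e.g. `fit$params`).
#' @return Scalar score (smaller is better).
#' @export
bic_score <- function(data, params) {
  2 * negative_log_pseudolikelihood(params, data) +
    log(data$n) * mgm_df(params)
}

#' BIC selection along a penalty path
#'
#' Fits the model at every path point (warm-started) and returns the
#' penalty minimizing [bic_score()].
#'
#' @param data A `mixed_dataset`.
#' @param path Decreasing penalty path.
#' @param ... Passed to [fit_coxmgm()].
#' @return List with `lambda` (a [penalty_vector()]), `scores`, `fits`.
#' @export
bic_select <- function(data, path, ...) {
  init <- NULL
  scores <- numeric(length(path))
  fits <- vector("list", length(path))
  for (k in seq_along(path)) {
    fit <- fit_coxmgm(data, path[k], init = init, ...)
    init <- fit$params
    fits[[k]] <- fit
    scores[k] <- bic_score(data, fit$params)
  }
  best <- which.min(scores)
  list(lambda = penalty_vector(path[best]), scores = scores, fits = fits,
       best = best)
}

#' Serialize a stability profile to JSON
#' @param profile A [stability_profile()].
#' @param path Output path.
#' @export
write_stability_profile <- function(profile, path) {
  jsonlite::write_json(list(path = profile$path,
                            instability = as.data.frame(profile$instability),
                            pooled = profile$pooled,
                            B = profile$B, b = profile$b, seed = profile$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
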
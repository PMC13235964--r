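## Internal layout shared by the partial-likelihood routines.
## Samples are sorted by ascending time; risk set at an event time includes all
## samples with time >= that event time (ties enter their own risk set).
cox_order <- function(time, status) {
  stopifnot(length(time) == length(status))
  if (any(time < 0)) stop("negative time")
  if (!all(status %in% c(0, 1))) stop("non-binary event indicator")
  if (sum(status) < 1) stop("zero observed events (degenerate risk sets)")
  ord <- order(time)
  list(ord = ord, t = time[ord], d = status[ord])
}

#' Cox partial log-likelihood, score, and Hessian diagonal in the linear predictor
#'
#' Computes the partial log-likelihood of a proportional hazards model as a
#' function of the linear predictor `eta`, together with its gradient and the
#' diagonal of its negative Hessian, with Efron's correction for tied event
#' times (or Breslow's convention on request).
#'
#' @param time Nonnegative observation times.
#' @param status Event indicators (1 = event observed, 0 = censored).
#' @param eta Linear predictor, same length as `time`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A list with `loglik`, `grad` (d loglik / d eta), and `hdiag`
#'   (diagonal of -d2 loglik / d eta2, all entries nonnegative).
#' @export
cox_partial <- function(time, status, eta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  pre <- cox_pre(time, status)
  cox_partial_pre(pre, eta, ties)
}

## Precompute the sort/risk-set structure once per (time, status) pair; the
## structure is reused across evaluations at different linear predictors.
## grp_last holds the last sorted index of each distinct time, so grouped
## sums are cumsum differences (no factors).
cox_pre <- function(time, status) {
  so <- cox_order(time, status)
  ut <- unique(so$t)                 # ascending
  gidx <- match(so$t, ut)
  G <- length(ut)
  is_ev <- so$d == 1
  k_g <- tabulate(gidx[is_ev], nbins = G)
  grp_last <- cumsum(tabulate(gidx, nbins = G))
  list(ord = so$ord, t = so$t, d = so$d, ut = ut, gidx = gidx, G = G,
       is_ev = is_ev, k_g = k_g, grp_last = grp_last,
       distinct = (G == length(so$t)), n = length(so$t))
}

## grouped sum of a sorted vector by distinct time: cumsum differences
## (identity when every time is distinct)
grp_sum <- function(v, grp_last) {
  if (length(grp_last) == length(v)) return(v)
  cs <- cumsum(v)[grp_last]
  c(cs[1L], diff(cs))
}

cox_partial_pre <- function(pre, eta, ties = "efron") {
  n <- pre$n
  stopifnot(length(eta) == n, all(is.finite(eta)))
  eta_s <- eta[pre$ord]
  eta_c <- eta_s - max(eta_s)        # overflow guard; invariant quantities
  e <- exp(eta_c)
  gidx <- pre$gidx
  G <- pre$G
  is_ev <- pre$is_ev
  k_g <- pre$k_g

  ## reverse-cumulative risk-set sums at each distinct time
  grp_e <- grp_sum(e, pre$grp_last)
  S0risk <- rev(cumsum(rev(grp_e)))  # length G
  tieS0 <- grp_sum(e * is_ev, pre$grp_last)

  H <- Hf <- H2 <- H2f <- H2ff <- rep(0, G)
  loglik <- 0
  ## untied event groups (k = 1): fully vectorized; Breslow = Efron there
  g1 <- which(k_g == 1L)
  if (length(g1)) {
    den1 <- S0risk[g1]
    loglik <- loglik - sum(log(den1))
    H[g1] <- 1 / den1
    H2[g1] <- 1 / den1^2
  }
  for (g in which(k_g > 1L)) {
    k <- k_g[g]
    f <- if (ties == "efron") (seq_len(k) - 1) / k else rep(0, k)
    denom <- S0risk[g] - f * tieS0[g]
    loglik <- loglik - sum(log(denom))
    H[g] <- sum(1 / denom)
    Hf[g] <- sum(f / denom)
    H2[g] <- sum(1 / denom^2)
    H2f[g] <- sum(f / denom^2)
    H2ff[g] <- sum(f^2 / denom^2)
  }
  loglik <- loglik + sum(eta_c[is_ev])
  ## undo centering: each event term eta_c = eta - max; each log denom shifted
  ## identically, so loglik is already the centered-consistent value; restore
  ## the absolute value for reporting:
  ## sum_D eta - sum log(exp(max)*denom_c) = sum_D eta_c - sum log denom_c.
  ## (both forms equal; nothing further to do)

  cumH <- cumsum(H)
  cumH2 <- cumsum(H2)
  A <- cumH[gidx]
  B2 <- cumH2[gidx]
  own_ev <- is_ev
  A[own_ev] <- A[own_ev] - Hf[gidx[own_ev]]
  B2[own_ev] <- B2[own_ev] - (2 * H2f[gidx[own_ev]] - H2ff[gidx[own_ev]])

  grad_s <- pre$d - e * A
  hdiag_s <- e * A - e^2 * B2
  hdiag_s[hdiag_s < 0] <- 0          # numerical guard; analytically >= 0

  grad <- numeric(n); hdiag <- numeric(n)
  grad[pre$ord] <- grad_s
  hdiag[pre$ord] <- hdiag_s
  list(loglik = loglik, grad = grad, hdiag = hdiag)
}

## Log-likelihood-only evaluation (backtracking fast path).
cox_loglik_pre <- function(pre, eta, ties = "efron") {
  eta_s <- eta[pre$ord]
  eta_c <- eta_s - max(eta_s)
  e <- exp(eta_c)
  S0risk <- rev(cumsum(rev(grp_sum(e, pre$grp_last))))
  tieS0 <- grp_sum(e * pre$is_ev, pre$grp_last)
  loglik <- sum(eta_c[pre$is_ev])
  g1 <- which(pre$k_g == 1L)
  if (length(g1)) loglik <- loglik - sum(log(S0risk[g1]))
  for (g in which(pre$k_g > 1L)) {
    k <- pre$k_g[g]
    f <- if (ties == "efron") (seq_len(k) - 1) / k else rep(0, k)
    loglik <- loglik - sum(log(S0risk[g] - f * tieS0[g]))
  }
  loglik
}

#' Second-order working quantities of the Cox partial likelihood
#'
#' Expands the negative Cox partial log-likelihood to second order around the
#' linear predictor `eta` and returns the score `lprime`, the Hessian diagonal
#' `ldouble`, the diagonal weight matrix `W` (as a vector, `diag(W) = ldouble`),
#' the working response `z = eta - lprime/ldouble`, and the product `Wz`.
#' At `eta = 0` under Breslow tie handling, `Wz` equals the Martingale
#' residuals of the null model.
#'
#' @inheritParams cox_partial
#' @return List with `loglik`, `lprime`, `ldouble`, `W`, `z`, `Wz`.
#' @export
cox_working_quantities <- function(time, status, eta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cp <- cox_partial(time, status, eta, ties = ties)
  lprime <- -cp$grad                 # gradient of the NEGATIVE log-likelihood
  W <- cp$hdiag
  z <- ifelse(W > 0, eta - lprime / W, eta)
  ## Wz = W*eta - lprime, with the W == 0 => lprime == 0 convention
  Wz <- W * eta - lprime
  list(loglik = -cp$loglik, lprime = lprime, ldouble = W, W = W, z = z, Wz = Wz)
}

#' Martingale residuals of the null Cox model
#'
#' `M_i = delta_i - Lambda(t_i)` where `Lambda` is the Nelson-Aalen (Breslow)
#' cumulative hazard of the covariate-free model. Residuals sum to zero.
#'
#' @inheritParams cox_partial
#' @return Numeric vector of residuals.
#' @export
martingale_residuals <- function(time, status) {
  so <- cox_order(time, status)
  n <- length(so$t)
  ut <- unique(so$t)
  gidx <- match(so$t, ut)
  atrisk <- rev(cumsum(rev(tabulate(gidx, nbins = length(ut)))))
  nev <- rep(0, length(ut))
  tb <- rowsum(as.numeric(so$d), gidx)
  nev[as.integer(rownames(tb))] <- tb[, 1L]
  haz <- nev / atrisk
  cumhaz <- cumsum(haz)[gidx]
  out <- numeric(n)
  out[so$ord] <- so$d - cumhaz
  out
}

## Efron/Breslow information matrix in the coefficients for design X.
## Uses reverse-cumulative sums of e*x and e*x x' per distinct time, then a
## loop over tied event groups; O(n p^2 + events p^2).
cox_information <- function(X, time, status, eta, ties = "efron",
                            pre = NULL) {
  if (is.null(pre)) pre <- cox_pre(time, status)
  n <- nrow(X); p <- ncol(X)
  Xs <- X[pre$ord, , drop = FALSE]
  eta_s <- eta[pre$ord]
  e <- exp(eta_s - max(eta_s))
  G <- pre$G
  is_ev <- pre$is_ev
  k_g <- pre$k_g
  gl <- pre$grp_last

  eX <- Xs * e
  ## p(p+1)/2 cross columns for the second moment
  ij <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  eXX <- eX[, ij[, 1L], drop = FALSE] * Xs[, ij[, 2L], drop = FALSE]

  revcum_cols <- function(M) {
    out <- matrix(0, G, ncol(M))
    for (j in seq_len(ncol(M)))
      out[, j] <- rev(cumsum(rev(grp_sum(M[, j], gl))))
    out
  }
  S0r <- rev(cumsum(rev(grp_sum(e, gl))))
  S1r <- revcum_cols(eX)
  S2r <- revcum_cols(eXX)

  ## tie-group sums over event rows (needed for tied groups only)
  S1t <- matrix(0, G, p)
  S2t <- matrix(0, G, ncol(eXX))
  S0t <- rep(0, G)
  if (any(k_g > 1L)) {
    S0t <- grp_sum(e * is_ev, gl)
    for (j in seq_len(p)) S1t[, j] <- grp_sum(eX[, j] * is_ev, gl)
    for (j in seq_len(ncol(eXX))) S2t[, j] <- grp_sum(eXX[, j] * is_ev, gl)
  }

  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[upper.tri(M, diag = TRUE)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  I <- matrix(0, p, p)
  ## untied event groups: vectorized over groups
  g1 <- which(k_g == 1L)
  if (length(g1)) {
    den1 <- S0r[g1]
    v2sum <- colSums(S2r[g1, , drop = FALSE] / den1)
    A1 <- S1r[g1, , drop = FALSE] / den1
    I <- I + unpack(v2sum) - crossprod(A1)
  }
  for (g in which(k_g > 1L)) {
    k <- k_g[g]
    f <- if (ties == "efron") (seq_len(k) - 1) / k else rep(0, k)
    for (l in seq_len(k)) {
      denom <- S0r[g] - f[l] * S0t[g]
      v1 <- S1r[g, ] - f[l] * S1t[g, ]
      v2 <- unpack(S2r[g, ] - f[l] * S2t[g, ])
      I <- I + v2 / denom - tcrossprod(v1) / denom^2
    }
  }
  I
}

#' Fit a Cox proportional hazards model by Newton-Raphson
#'
#' Maximizes the Efron-corrected partial likelihood with step-halving.
#' This fitter backs both the conditional-independence tests and the
#' Markov-blanket predictors.
#'
#' @param X Numeric design matrix (n x p); `p = 0` gives the null model.
#' @param time,status Survival outcome.
#' @param ties Tie convention, `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `"coxmgm_coxfit"` with elements `coef`, `se`,
#'   `vcov`, `loglik`, `loglik_null`, `n_events`, `iter`, `converged`.
#' @export
cox_fit <- function(X, time, status, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  n <- length(time)
  pre <- cox_pre(time, status)
  ll_null <- cox_partial_pre(pre, rep(0, n), ties = ties)$loglik
  if (ncol(X) == 0L) {
    return(structure(list(coef = numeric(0), se = numeric(0),
                          vcov = matrix(0, 0, 0),
                          loglik = ll_null, loglik_null = ll_null,
                          n_events = sum(status), iter = 0L, converged = TRUE,
                          time = time, status = status, ties = ties, X = X),
                     class = "coxmgm_coxfit"))
  }
  stopifnot(nrow(X) == n)
  beta <- rep(0, ncol(X))
  ll <- ll_null
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    cp <- cox_partial_pre(pre, eta, ties = ties)
    g <- drop(crossprod(X, cp$grad))
    I <- cox_information(X, time, status, eta, ties = ties, pre = pre)
    step <- tryCatch(solve(I, g), error = function(e) stop("singular design"))
    lambda_step <- 1
    repeat {
      beta_new <- beta + lambda_step * step
      ll_new <- tryCatch(
        cox_loglik_pre(pre, drop(X %*% beta_new), ties = ties),
        error = function(e) -Inf)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda_step <- lambda_step / 2
      if (lambda_step < 1e-10) stop("non-convergence (step-halving exhausted)")
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new
    ll <- ll_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  I <- cox_information(X, time, status, eta, ties = ties, pre = pre)
  V <- tryCatch(solve(I), error = function(e) stop("singular design"))
  structure(list(coef = beta, se = sqrt(pmax(diag(V), 0)), vcov = V,
                 loglik = ll, loglik_null = ll_null,
                 n_events = sum(status), iter = iter, converged = converged,
                 time = time, status = status, ties = ties, X = X),
            class = "coxmgm_coxfit")
}

#' @export
print.coxmgm_coxfit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties)\n", sep = "")
  cat("  events:", x$n_events, " loglik:", format(x$loglik), "\n")
  if (length(x$coef)) {
    print(data.frame(coef = x$coef, se = x$se, hr = exp(x$coef),
                     row.names = colnames(x$X)))
  } else cat("  (null model)\n")
  invisible(x)
}

## Breslow baseline cumulative hazard at a fitted linear predictor.
breslow_cumhaz <- function(time, status, eta) {
  so <- cox_order(time, status)
  e <- exp(eta[so$ord] - mean(eta))
  ut <- unique(so$t)
  gidx <- match(so$t, ut)
  S0 <- rev(cumsum(rev(rowsum(e, gidx)[, 1L])))
  nev <- rep(0, length(ut))
  tb <- rowsum(as.numeric(so$d), gidx)
  nev[as.integer(rownames(tb))] <- tb[, 1L]
  data.frame(time = ut, cumhaz = cumsum(nev / S0) * exp(-mean(eta)))
}
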
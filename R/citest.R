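## Conditional-independence testing over mixed data with censored variables.
##
## Censored variables are handled on either side of the test:
##  * as the tested variable, via Cox regression (Wald t-test for a
##    continuous partner, likelihood-ratio test for a discrete partner);
##  * inside the conditioning set, via the null-model Martingale residuals
##    M_i = delta_i - Lambda(t_i), which represent the censored covariate
##    without dropping censored rows and without expansion bias.

#' Configuration for conditional-independence testing
#'
#' @param alpha Significance level in (0, 1).
#' @param max_cond_size Maximum conditioning-set size (depth bound).
#' @param ties Tie-handling for Cox fits: `"efron"` or `"breslow"`.
#' @return An object of class `"ci_config"`.
#' @export
ci_config <- function(alpha = 0.05, max_cond_size = 3L,
                      ties = c("efron", "breslow")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, max_cond_size = as.integer(max_cond_size),
                 ties = match.arg(ties)),
            class = "ci_config")
}

ci_result <- function(p_value, statistic, df = NA_real_, family, n_eff) {
  p_value <- min(max(unname(p_value), 0), 1)
  structure(list(p_value = p_value, statistic = unname(statistic),
                 df = unname(df), family = family, n_eff = n_eff),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("ci_result [%s]: stat = %.4g, df = %s, p = %.4g (n = %d)\n",
              x$family, x$statistic, format(x$df), x$p_value, x$n_eff))
  invisible(x)
}

## column(s) of a variable by name, for regression use
var_kind <- function(data, v) dataset_var_kinds(data)[[v]]

#' Expand a conditioning set into a design matrix
#'
#' Continuous members pass through; discrete members are reference-encoded;
#' censored members are replaced by the Martingale residuals of their null
#' Cox model. All n rows are retained.
#'
#' @param S Character vector of conditioning variable names (possibly empty).
#' @param data A `mixed_dataset`.
#' @param cache Optional environment memoizing per-variable expansion
#'   columns (used by [ci_tester()] to avoid recomputing Martingale
#'   residuals and encodings across thousands of tests).
#' @return Numeric matrix with n rows (0 columns for empty `S`).
#' @export
expand_conditioning_set <- function(S, data, cache = NULL) {
  out <- matrix(0, data$n, 0)
  for (v in S) {
    if (!is.null(cache) && !is.null(cache[[v]])) {
      out <- cbind(out, cache[[v]])
      next
    }
    k <- var_kind(data, v)
    col <- switch(k,
      continuous = {
        m <- data$continuous[, v, drop = FALSE]
        colnames(m) <- v
        m
      },
      discrete = {
        m <- indicator_matrix(data$discrete[[v]], reference = TRUE)
        colnames(m) <- paste0(v, ".", colnames(m))
        m
      },
      censored = {
        if (sum(data$event[, v]) < 1)
          stop("censored conditioning variable '", v, "' has zero events")
        m <- matrix(martingale_residuals(data$time[, v], data$event[, v]))
        colnames(m) <- paste0(v, ".mres")
        m
      })
    if (!is.null(cache)) cache[[v]] <- col
    out <- cbind(out, col)
  }
  out
}

## Drop linearly dependent columns (protects LRT dfs in degenerate designs).
drop_aliased <- function(Xm) {
  if (ncol(Xm) == 0L) return(Xm)
  qr_ <- qr(cbind(1, Xm))
  keep <- qr_$pivot[seq_len(qr_$rank)]
  keep <- setdiff(keep, 1L) - 1L
  Xm[, sort(keep), drop = FALSE]
}

#' Test a censored variable against a continuous variable
#'
#' Fits `Cox(X ~ Y + expand(S))` by Newton-Raphson with Efron ties and
#' refers the Wald statistic for Y's coefficient to a t distribution with
#' (events - parameters) degrees of freedom.
#'
#' @param x Censored variable name. @param y Continuous variable name.
#' @param S Conditioning set (character vector).
#' @param data A `mixed_dataset`.
#' @param config A [ci_config()].
#' @return A `ci_result`.
#' @export
test_censored_vs_continuous <- function(x, y, S, data, config = ci_config(),
                                        cache = NULL) {
  Z <- expand_conditioning_set(S, data, cache)
  Xd <- cbind(Y = data$continuous[, y], Z)
  fit <- cox_fit(Xd, data$time[, x], data$event[, x], ties = config$ties)
  tstat <- fit$coef[1L] / fit$se[1L]
  df <- max(fit$n_events - ncol(Xd), 1L)
  p <- 2 * stats::pt(-abs(tstat), df)
  ci_result(p, tstat, df, "censored-continuous (Cox Wald t)", data$n)
}

#' Test a censored variable against a discrete variable
#'
#' Likelihood-ratio test between `Cox(X ~ expand(S))` and
#' `Cox(X ~ Y + expand(S))` (Y reference-encoded), referred to chi-squared
#' with L-1 degrees of freedom.
#'
#' @inheritParams test_censored_vs_continuous
#' @param y Discrete variable name.
#' @export
test_censored_vs_discrete <- function(x, y, S, data, config = ci_config(),
                                      cache = NULL) {
  yf <- data$discrete[[y]]
  if (length(unique(as.integer(yf))) < 2L) stop("Y is constant")
  Z <- expand_conditioning_set(S, data, cache)
  Ym <- indicator_matrix(yf, reference = TRUE)
  nkey <- paste0(".coxnull|", x, "|", paste(sort(S), collapse = ","))
  null_ll <- if (!is.null(cache) && !is.null(cache[[nkey]])) cache[[nkey]]
  else {
    ll <- cox_fit(Z, data$time[, x], data$event[, x], ties = config$ties)$loglik
    if (!is.null(cache)) cache[[nkey]] <- ll
    ll
  }
  full_fit <- cox_fit(cbind(Ym, Z), data$time[, x], data$event[, x],
                      ties = config$ties)
  stat <- max(2 * (full_fit$loglik - null_ll), 0)
  df <- ncol(Ym)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  ci_result(p, stat, df, "censored-discrete (Cox LRT)", data$n)
}

## Gaussian LRT for adding columns A to a linear model of x on Z.
gaussian_lrt <- function(xv, Z, A, n) {
  f0 <- stats::lm.fit(cbind(1, Z), xv)
  A1 <- drop_aliased(cbind(Z, A))
  f1 <- stats::lm.fit(cbind(1, A1), xv)
  df <- (ncol(A1) - ncol(Z))
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  stat <- max(n * log(rss0 / rss1), 0)
  list(stat = stat, df = df)
}

#' Multinomial logistic regression by Newton-Raphson
#'
#' Reference-level parameterization; returns the deviance and coefficient
#' matrix. Written for the tight inner loop of the discrete-discrete
#' conditional-independence tests, where thousands of small multinomial
#' fits are required.
#'
#' @param X Numeric covariate matrix (no intercept column; one is added).
#' @param y A factor.
#' @param max_iter,tol Newton controls.
#' @return List with `deviance`, `coef` ((p+1) x (L-1)), `iter`.
#' @export
multinom_fit <- function(X, y, max_iter = 50L, tol = 1e-8) {
  y <- droplevels(as.factor(y))
  L <- nlevels(y)
  if (L < 2L) stop("response has a single observed level")
  X1 <- cbind(1, X)
  n <- nrow(X1); p <- ncol(X1)
  Y <- matrix(0, n, L)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, p, L - 1L)
  loglik <- function(B) {
    Eta <- X1 %*% B
    lse <- log1p(rowSums(exp(Eta)))     # base level logit 0
    sum(Eta[cbind(seq_len(n), pmax(as.integer(y) - 1L, 1L))] *
          (as.integer(y) > 1L)) - sum(lse)
  }
  ll <- loglik(B)
  for (it in seq_len(max_iter)) {
    Eta <- X1 %*% B
    E <- exp(Eta)
    denom <- 1 + rowSums(E)
    P <- E / denom                      # n x (L-1)
    G <- crossprod(X1, Y[, -1L, drop = FALSE] - P)   # p x (L-1)
    ## block Hessian: H[(a),(b)] = X' diag(P_a (1[a==b] - P_b)) X
    H <- matrix(0, p * (L - 1L), p * (L - 1L))
    for (a in seq_len(L - 1L)) for (b in a:(L - 1L)) {
      w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      blk <- crossprod(X1 * w, X1)
      ia <- (a - 1L) * p + seq_len(p); ib <- (b - 1L) * p + seq_len(p)
      H[ia, ib] <- blk
      H[ib, ia] <- t(blk)
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), as.numeric(G)),
                     error = function(e) stop("singular design"))
    sz <- 1
    repeat {
      Bn <- B + sz * matrix(step, p, L - 1L)
      lln <- loglik(Bn)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-10) stop("non-convergence (step-halving exhausted)")
    }
    conv <- abs(lln - ll) < tol * (abs(ll) + 1)
    B <- Bn; ll <- lln
    if (conv) break
  }
  list(deviance = -2 * ll, coef = B, iter = it)
}

## multinomial LRT: add columns A to a multinomial model of factor f on Z.
## The null deviance is cached under null_key (it recurs across partner
## variables during constraint-based search).
multinom_lrt <- function(f, Z, A, cache = NULL, null_key = NULL) {
  A1 <- drop_aliased(cbind(Z, A))
  d0 <- if (!is.null(cache) && !is.null(null_key) &&
            !is.null(cache[[null_key]])) cache[[null_key]]
  else {
    dv <- multinom_fit(Z, f)$deviance
    if (!is.null(cache) && !is.null(null_key)) cache[[null_key]] <- dv
    dv
  }
  d1 <- multinom_fit(A1, f)$deviance
  list(stat = max(d0 - d1, 0), added = ncol(A1) - ncol(Z))
}

#' Test two non-censored variables (conditioning set may contain censored)
#'
#' On the expanded conditioning design: continuous-continuous uses the Wald
#' t-test on the partner's coefficient in a linear model (equivalently the
#' partial-correlation t-test); continuous-discrete uses a Gaussian
#' likelihood-ratio test adding the discrete variable to the model of the
#' continuous one (chi-squared, L-1 df); discrete-discrete uses multinomial
#' likelihood-ratio tests in both directions, symmetrized by the larger
#' p-value (chi-squared, (Lx-1)(Ly-1) df).
#'
#' @inheritParams test_censored_vs_continuous
#' @param x,y Continuous or discrete variable names.
#' @export
test_noncensored <- function(x, y, S, data, config = ci_config(),
                             cache = NULL) {
  kx <- var_kind(data, x); ky <- var_kind(data, y)
  Z <- expand_conditioning_set(S, data, cache)
  n <- data$n
  if (kx == "continuous" && ky == "continuous") {
    X1 <- cbind(1, Y = data$continuous[, y], Z)
    fit <- stats::lm.fit(X1, data$continuous[, x])
    res <- fit$residuals
    dfres <- n - ncol(X1)
    sigma2 <- sum(res^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(X1)))
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    tstat <- fit$coefficients[2L] / se
    p <- 2 * stats::pt(-abs(tstat), dfres)
    return(ci_result(p, tstat, dfres, "continuous-continuous (partial t)", n))
  }
  if (kx == "discrete" && ky == "discrete") {
    fx <- data$discrete[[x]]; fy <- data$discrete[[y]]
    Ax <- indicator_matrix(fx, reference = TRUE)
    Ay <- indicator_matrix(fy, reference = TRUE)
    skey <- paste(sort(S), collapse = ",")
    l1 <- multinom_lrt(fx, Z, Ay, cache, paste0(".mdev|", x, "|", skey))
    l2 <- multinom_lrt(fy, Z, Ax, cache, paste0(".mdev|", y, "|", skey))
    Lx <- length(unique(as.integer(fx)))
    Ly <- length(unique(as.integer(fy)))
    df <- (Lx - 1) * (Ly - 1)
    p1 <- stats::pchisq(l1$stat, df, lower.tail = FALSE)
    p2 <- stats::pchisq(l2$stat, df, lower.tail = FALSE)
    if (p1 >= p2) return(ci_result(p1, l1$stat, df, "discrete-discrete (LRT)", n))
    return(ci_result(p2, l2$stat, df, "discrete-discrete (LRT)", n))
  }
  ## mixed: always model the continuous one, add the discrete one
  cont <- if (kx == "continuous") x else y
  disc <- if (kx == "continuous") y else x
  A <- indicator_matrix(data$discrete[[disc]], reference = TRUE)
  lr <- gaussian_lrt(data$continuous[, cont], Z, A, n)
  p <- stats::pchisq(lr$stat, lr$df, lower.tail = FALSE)
  ci_result(p, lr$stat, lr$df, "continuous-discrete (Gaussian LRT)", n)
}

#' Conditional-independence test dispatcher
#'
#' Routes by the kinds of `x` and `y`: censored-vs-continuous (Cox Wald
#' t-test), censored-vs-discrete (Cox LRT), or the base mixed test. When
#' both are censored, each is tested as the Cox target with the other
#' entering as a Martingale-residual covariate, and the larger p-value is
#' returned. Symmetric in its arguments by construction.
#'
#' @param x,y Variable names.
#' @param S Conditioning set (character vector, possibly empty).
#' @param data A `mixed_dataset`.
#' @param config A [ci_config()].
#' @return A `ci_result`.
#' @export
ci_test <- function(x, y, S, data, config = ci_config(), cache = NULL) {
  if (x %in% S || y %in% S) stop("conditioning set must exclude x and y")
  kx <- var_kind(data, x); ky <- var_kind(data, y)
  if (kx == "censored" && ky == "censored") {
    r1 <- test_censored_vs_martingale(x, y, S, data, config, cache)
    r2 <- test_censored_vs_martingale(y, x, S, data, config, cache)
    return(if (r1$p_value >= r2$p_value) r1 else r2)
  }
  if (kx == "censored") {
    if (ky == "continuous")
      return(test_censored_vs_continuous(x, y, S, data, config, cache))
    return(test_censored_vs_discrete(x, y, S, data, config, cache))
  }
  if (ky == "censored") {
    if (kx == "continuous")
      return(test_censored_vs_continuous(y, x, S, data, config, cache))
    return(test_censored_vs_discrete(y, x, S, data, config, cache))
  }
  test_noncensored(x, y, S, data, config, cache)
}

## censored target x, censored partner y represented by Martingale residuals
test_censored_vs_martingale <- function(x, y, S, data, config, cache = NULL) {
  Z <- expand_conditioning_set(S, data, cache)
  Ym <- if (!is.null(cache) && !is.null(cache[[paste0(".mres.", y)]])) {
    cache[[paste0(".mres.", y)]]
  } else {
    mr <- martingale_residuals(data$time[, y], data$event[, y])
    if (!is.null(cache)) cache[[paste0(".mres.", y)]] <- mr
    mr
  }
  Xd <- cbind(Y = Ym, Z)
  fit <- cox_fit(Xd, data$time[, x], data$event[, x], ties = config$ties)
  tstat <- fit$coef[1L] / fit$se[1L]
  df <- max(fit$n_events - ncol(Xd), 1L)
  p <- 2 * stats::pt(-abs(tstat), df)
  ci_result(p, tstat, df, "censored-censored (Cox Wald t on residuals)", data$n)
}
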
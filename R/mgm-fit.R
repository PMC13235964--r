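## CoxMGM: undirected mixed graphical model over continuous (x), discrete
## (y), and censored (t, delta) variables, fit by penalized negative
## log-pseudolikelihood.
##
## Node conditionals: Gaussian linear regression (unit variance on
## standardized data) for continuous nodes, multinomial logistic regression
## for discrete nodes, Cox partial likelihood (Efron ties) for censored
## nodes. Censored variables enter the continuous and discrete conditionals
## through the null-model working term Wz, i.e. their Martingale residuals;
## each censored node's own conditional is the exact partial likelihood of
## its linear predictor in the other variables. Edge parameters are shared
## between the two endpoint conditionals (standard pseudolikelihood
## construction).

#' Edge-type penalty vector
#'
#' The model penalizes each edge type separately: `cc` (|beta|, lasso),
#' `cd` (group l2 on rho), `dd` (Frobenius on phi), `sc` (|gamma|, lasso),
#' `sd` (group l2 on psi).
#'
#' @param lambda A single nonnegative value (broadcast to all five) or a
#'   length-5 vector in the order cc, cd, dd, sc, sd.
#' @return Named numeric vector of length 5.
#' @export
penalty_vector <- function(lambda) {
  if (length(lambda) == 1L) lambda <- rep(lambda, 5L)
  if (length(lambda) != 5L) stop("penalty vector needs 1 or 5 values")
  if (any(lambda < 0)) stop("negative penalty")
  stats::setNames(as.numeric(lambda), c("cc", "cd", "dd", "sc", "sd"))
}

mgm_dims <- function(data) {
  L <- if (data$q > 0) unname(vapply(data$discrete, nlevels, 1L)) else integer(0)
  list(p = data$p, q = data$q, r = data$r, L = L)
}

## Zero-initialized parameter set.
mgm_params_zero <- function(dims) {
  p <- dims$p; q <- dims$q; r <- dims$r; L <- dims$L
  list(
    alpha = rep(0, p),
    beta = matrix(0, p, p),
    rho = lapply(seq_len(q), function(j) matrix(0, p, L[j])),
    phi = if (q > 1) {
      out <- vector("list", q)
      for (j in seq_len(q - 1L)) {
        out[[j]] <- vector("list", q)
        for (k in (j + 1L):q) out[[j]][[k]] <- matrix(0, L[j], L[k])
      }
      out
    } else vector("list", q),
    gamma = matrix(0, p, r),
    psi = lapply(seq_len(q), function(j) matrix(0, L[j], r)),
    disc_int = lapply(seq_len(q), function(j) rep(0, L[j])),
    dims = dims
  )
}

## Model frame: standardized design blocks + fixed Martingale-residual
## representation of censored variables.
mgm_frame <- function(data, standardize = TRUE) {
  if (standardize) data <- standardize_continuous(data)
  X <- data$continuous
  D <- lapply(data$discrete, indicator_matrix)
  M <- matrix(0, data$n, data$r)
  pre <- vector("list", data$r)
  if (data$r > 0) {
    for (m in seq_len(data$r)) {
      M[, m] <- martingale_residuals(data$time[, m], data$event[, m])
      pre[[m]] <- cox_pre(data$time[, m], data$event[, m])
    }
    colnames(M) <- colnames(data$time)
  }
  list(X = X, D = D, M = M, time = data$time, event = data$event,
       pre = pre, n = data$n, data = data)
}

## Forward pass: linear predictors of every node conditional.
mgm_forward <- function(params, frame) {
  p <- params$dims$p; q <- params$dims$q; r <- params$dims$r
  n <- frame$n
  mu <- NULL
  if (p > 0) {
    mu <- matrix(rep(params$alpha, each = n), n, p)
    if (p > 1) mu <- mu + frame$X %*% params$beta
    for (j in seq_len(q)) mu <- mu + frame$D[[j]] %*% t(params$rho[[j]])
    if (r > 0) mu <- mu + frame$M %*% t(params$gamma)
  }
  Eta <- vector("list", q)
  for (j in seq_len(q)) {
    E <- matrix(rep(params$disc_int[[j]], each = n), n, params$dims$L[j])
    if (p > 0) E <- E + frame$X %*% params$rho[[j]]
    for (k in seq_len(q)) {
      if (k == j) next
      E <- E + if (j < k) frame$D[[k]] %*% t(params$phi[[j]][[k]])
      else frame$D[[k]] %*% params$phi[[k]][[j]]
    }
    if (r > 0) E <- E + frame$M %*% t(params$psi[[j]])
    Eta[[j]] <- E
  }
  eta_cens <- matrix(0, n, r)
  for (m in seq_len(r)) {
    em <- rep(0, n)
    if (p > 0) em <- em + drop(frame$X %*% params$gamma[, m])
    for (j in seq_len(q)) em <- em + drop(frame$D[[j]] %*% params$psi[[j]][, m])
    eta_cens[, m] <- em
  }
  list(mu = mu, Eta = Eta, eta_cens = eta_cens)
}

## Smooth part of the objective (sum of node-conditional negative
## log-likelihoods); optionally also its gradient in all parameters.
mgm_smooth <- function(params, frame, gradient = FALSE) {
  p <- params$dims$p; q <- params$dims$q; r <- params$dims$r
  n <- frame$n
  fw <- mgm_forward(params, frame)
  value <- 0
  if (p > 0) {
    Eres <- fw$mu - frame$X
    value <- value + 0.5 * sum(Eres^2) + n * p * 0.5 * log(2 * pi)
  }
  Rlist <- vector("list", q)
  for (j in seq_len(q)) {
    E <- fw$Eta[[j]]
    mx <- E[, 1L]
    for (l in seq_len(ncol(E))[-1L]) mx <- pmax(mx, E[, l])
    lse <- mx + log(rowSums(exp(E - mx)))
    value <- value + sum(lse) - sum(E[frame$D[[j]] == 1])
    if (gradient) {
      P <- exp(E - lse)
      Rlist[[j]] <- P - frame$D[[j]]
    }
  }
  Geta <- if (gradient) matrix(0, n, r) else NULL
  for (m in seq_len(r)) {
    if (gradient) {
      cp <- cox_partial_pre(frame$pre[[m]], fw$eta_cens[, m], ties = "efron")
      value <- value - cp$loglik
      Geta[, m] <- -cp$grad
    } else {
      value <- value - cox_loglik_pre(frame$pre[[m]], fw$eta_cens[, m],
                                      ties = "efron")
    }
  }
  value <- as.numeric(value)
  if (!gradient) return(list(value = value))

  g <- mgm_params_zero(params$dims)
  if (p > 0) {
    g$alpha <- colSums(Eres)
    if (p > 1) {
      M0 <- crossprod(frame$X, Eres)
      G <- M0 + t(M0)
      diag(G) <- 0
      g$beta <- G
    }
    for (j in seq_len(q))
      g$rho[[j]] <- crossprod(frame$X, Rlist[[j]]) + crossprod(Eres, frame$D[[j]])
    if (r > 0) g$gamma <- crossprod(Eres, frame$M) + crossprod(frame$X, Geta)
  } else {
    for (j in seq_len(q)) g$rho[[j]] <- matrix(0, 0, params$dims$L[j])
  }
  for (j in seq_len(q)) {
    g$disc_int[[j]] <- colSums(Rlist[[j]])
    if (r > 0)
      g$psi[[j]] <- crossprod(Rlist[[j]], frame$M) + crossprod(frame$D[[j]], Geta)
    if (j < q) for (k in (j + 1L):q)
      g$phi[[j]][[k]] <- crossprod(Rlist[[j]], frame$D[[k]]) +
        crossprod(frame$D[[j]], Rlist[[k]])
  }
  list(value = value, grad = g)
}

#' Negative log-pseudolikelihood of a CoxMGM parameter set
#'
#' Sum of the node-conditional negative log-likelihoods: Gaussian (unit
#' variance) for continuous nodes, multinomial logistic for discrete nodes,
#' Cox partial likelihood with Efron ties for censored nodes.
#'
#' @param params An `mgm_params` list (see [fit_coxmgm()]).
#' @param data A `mixed_dataset`.
#' @param standardize Standardize continuous columns first (default TRUE,
#'   matching the fitting convention).
#' @return Scalar value.
#' @export
negative_log_pseudolikelihood <- function(params, data, standardize = TRUE) {
  dims <- mgm_dims(data)
  if (!identical(dims[c("p", "q", "r")], params$dims[c("p", "q", "r")]))
    stop("dimension mismatch between params and data")
  frame <- mgm_frame(data, standardize = standardize)
  mgm_smooth(params, frame)$value
}

mgm_penalty <- function(params, lambda) {
  p <- params$dims$p; q <- params$dims$q; r <- params$dims$r
  pen <- 0
  if (p > 1) pen <- pen + lambda["cc"] * sum(abs(params$beta[upper.tri(params$beta)]))
  for (j in seq_len(q))
    if (p > 0) pen <- pen + lambda["cd"] * sum(sqrt(rowSums(params$rho[[j]]^2)))
  if (q > 1) for (j in seq_len(q - 1L)) for (k in (j + 1L):q)
    pen <- pen + lambda["dd"] * sqrt(sum(params$phi[[j]][[k]]^2))
  if (r > 0) {
    if (p > 0) pen <- pen + lambda["sc"] * sum(abs(params$gamma))
    for (j in seq_len(q))
      pen <- pen + lambda["sd"] * sum(sqrt(colSums(params$psi[[j]]^2)))
  }
  as.numeric(pen)
}

#' Penalized CoxMGM objective
#'
#' [negative_log_pseudolikelihood()] plus the five edge-type penalties:
#' lasso on beta (cc) and gamma (sc), group l2 on rho (cd) and psi (sd),
#' Frobenius on phi (dd).
#'
#' @inheritParams negative_log_pseudolikelihood
#' @param penalties A [penalty_vector()] (or value accepted by it).
#' @return Scalar value.
#' @export
penalized_objective <- function(params, data, penalties, standardize = TRUE) {
  lambda <- penalty_vector(penalties)
  negative_log_pseudolikelihood(params, data, standardize = standardize) +
    mgm_penalty(params, lambda)
}

soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
group_soft <- function(v, t) {
  nv <- sqrt(sum(v^2))
  if (nv <= t) v * 0 else v * (1 - t / nv)
}

## Proximal operator of the penalty at step size stepsz.
mgm_prox <- function(params, stepsz, lambda) {
  p <- params$dims$p; q <- params$dims$q; r <- params$dims$r
  if (p > 1) {
    B <- soft(params$beta, stepsz * lambda["cc"])
    diag(B) <- 0
    params$beta <- B
  }
  for (j in seq_len(q)) if (p > 0) {
    rho <- params$rho[[j]]
    nv <- sqrt(rowSums(rho^2))
    sc <- ifelse(nv > stepsz * lambda["cd"], 1 - stepsz * lambda["cd"] / nv, 0)
    params$rho[[j]] <- rho * sc
  }
  if (q > 1) for (j in seq_len(q - 1L)) for (k in (j + 1L):q)
    params$phi[[j]][[k]] <- group_soft(params$phi[[j]][[k]], stepsz * lambda["dd"])
  if (r > 0) {
    if (p > 0) params$gamma <- soft(params$gamma, stepsz * lambda["sc"])
    for (j in seq_len(q)) {
      psi <- params$psi[[j]]
      nv <- sqrt(colSums(psi^2))
      sc <- ifelse(nv > stepsz * lambda["sd"], 1 - stepsz * lambda["sd"] / nv, 0)
      params$psi[[j]] <- sweep(psi, 2L, sc, `*`)
    }
  }
  params
}

## Flat-vector helpers for step-size bookkeeping. The shared symmetric beta
## block enters once (upper triangle) so inner products and norms are taken
## in the canonical parameter space.
mgm_pack <- function(params) {
  unlist(list(params$alpha, params$beta[upper.tri(params$beta)],
              params$rho, params$gamma,
              params$psi, params$disc_int,
              lapply(params$phi, function(x) unlist(x))), use.names = FALSE)
}

mgm_axpy <- function(a, x, y) {
  ## a*x + y over all parameter fields
  out <- y
  out$alpha <- a * x$alpha + y$alpha
  out$beta <- a * x$beta + y$beta
  out$gamma <- a * x$gamma + y$gamma
  q <- y$dims$q
  for (j in seq_len(q)) {
    out$rho[[j]] <- a * x$rho[[j]] + y$rho[[j]]
    out$psi[[j]] <- a * x$psi[[j]] + y$psi[[j]]
    out$disc_int[[j]] <- a * x$disc_int[[j]] + y$disc_int[[j]]
    if (j < q) for (k in (j + 1L):q)
      out$phi[[j]][[k]] <- a * x$phi[[j]][[k]] + y$phi[[j]][[k]]
  }
  out
}

#' Fit a Cox mixed graphical model
#'
#' Minimizes the penalized negative log-pseudolikelihood by proximal
#' gradient descent with backtracking line search: scalar soft-thresholding
#' for beta/gamma, group soft-thresholding for rho/psi/phi. The objective
#' sequence is non-increasing; iteration stops when the relative objective
#' change falls below `tol` or at `max_iter`.
#'
#' @param data A `mixed_dataset`.
#' @param penalties A [penalty_vector()] (single value broadcasts).
#' @param tol Relative objective-change tolerance (default 1e-5).
#' @param max_iter Iteration cap (default 500).
#' @param standardize Standardize continuous columns (default TRUE).
#' @param init Optional warm-start parameter set.
#' @return An object of class `"coxmgm_fit"`: `params`, `objective` (per
#'   iteration), `converged`, `iter`, `penalties`, `data_names`, `kinds`.
#' @export
fit_coxmgm <- function(data, penalties, tol = 1e-5, max_iter = 500L,
                       standardize = TRUE, init = NULL) {
  if (data$n < 2) stop("need at least 2 samples")
  lambda <- penalty_vector(penalties)
  frame <- mgm_frame(data, standardize = standardize)
  if (data$r > 0) for (m in seq_len(data$r))
    if (sum(data$event[, m]) < 1)
      stop("censored node ", colnames(data$time)[m], " has zero observed events")
  dims <- mgm_dims(data)
  params <- if (is.null(init)) mgm_params_zero(dims) else init

  sm <- mgm_smooth(params, frame, gradient = TRUE)
  Fcur <- sm$value + mgm_penalty(params, lambda)
  obj <- Fcur
  stepsz <- 1 / frame$n
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- sm$grad
    repeat {
      cand <- mgm_axpy(-stepsz, g, params)
      cand <- mgm_prox(cand, stepsz, lambda)
      dvec <- mgm_pack(cand) - mgm_pack(params)
      quad <- sm$value + sum(mgm_pack(g) * dvec) + sum(dvec^2) / (2 * stepsz)
      val <- mgm_smooth(cand, frame)$value
      if (!is.finite(val)) stop("divergence (objective NaN/Inf) at iteration ", it)
      if (val <= quad + 1e-9 * abs(quad)) break
      stepsz <- stepsz / 2
      if (stepsz < 1e-14) break
    }
    Fnew <- val + mgm_penalty(cand, lambda)
    if (Fnew <= Fcur + 1e-12) {
      params <- cand
      relchg <- (Fcur - Fnew) / (abs(Fcur) + 1e-10)
      Fcur <- Fnew
      obj <- c(obj, Fcur)
      if (relchg < tol) { converged <- TRUE; break }
    } else {
      ## prox step no longer improves at the smallest step: stationary
      converged <- TRUE
      break
    }
    sm <- mgm_smooth(params, frame, gradient = TRUE)
    stepsz <- stepsz * 2
  }
  structure(list(params = params, objective = obj, converged = converged,
                 iter = length(obj) - 1L, penalties = lambda,
                 var_names = dataset_var_names(data),
                 kinds = dataset_var_kinds(data)),
            class = "coxmgm_fit")
}

#' @export
print.coxmgm_fit <- function(x, ...) {
  cat("CoxMGM fit:", length(x$var_names), "variables;",
      x$iter, "iterations;",
      if (x$converged) "converged" else "max_iter reached", "\n")
  cat("  penalties:", paste(names(x$penalties), format(x$penalties), sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' Extract the undirected graph from fitted CoxMGM parameters
#'
#' An edge is present iff the norm of its parameter block exceeds
#' `zero_tol`: |beta_st| (cc), ||rho_sj||2 (cd), ||phi_jk||F (dd),
#' |gamma_sm| (sc), ||psi_jm||2 (sd).
#'
#' @param fit A `"coxmgm_fit"` (or an `mgm_params` list with `var_names` and
#'   `kinds` passed explicitly).
#' @param zero_tol Threshold on block norms (default 1e-6).
#' @param var_names,kinds Overrides when passing a bare parameter list.
#' @return An `endpoint_graph` (skeleton) over all p+q+r variables.
#' @export
params_to_graph <- function(fit, zero_tol = 1e-6, var_names = NULL, kinds = NULL) {
  if (inherits(fit, "coxmgm_fit")) {
    params <- fit$params
    var_names <- fit$var_names
    kinds <- fit$kinds
  } else params <- fit
  dims <- params$dims
  p <- dims$p; q <- dims$q; r <- dims$r
  g <- endpoint_graph(var_names, kinds = kinds, gclass = "skeleton")
  cn <- function(i) i                  # continuous index
  dn <- function(j) p + j              # discrete index
  sn <- function(m) p + q + m          # censored index
  if (p > 1) for (s in seq_len(p - 1L)) for (t in (s + 1L):p)
    if (abs(params$beta[s, t]) > zero_tol) g <- add_edge(g, cn(s), cn(t))
  for (s in seq_len(p)) for (j in seq_len(q))
    if (sqrt(sum(params$rho[[j]][s, ]^2)) > zero_tol) g <- add_edge(g, cn(s), dn(j))
  if (q > 1) for (j in seq_len(q - 1L)) for (k in (j + 1L):q)
    if (sqrt(sum(params$phi[[j]][[k]]^2)) > zero_tol) g <- add_edge(g, dn(j), dn(k))
  if (r > 0) {
    for (s in seq_len(p)) for (m in seq_len(r))
      if (abs(params$gamma[s, m]) > zero_tol) g <- add_edge(g, cn(s), sn(m))
    for (j in seq_len(q)) for (m in seq_len(r))
      if (sqrt(sum(params$psi[[j]][, m]^2)) > zero_tol) g <- add_edge(g, dn(j), sn(m))
  }
  g
}

## Count of free nonzero parameters (interactions by block support,
## plus unpenalized intercepts) for BIC.
mgm_df <- function(params, zero_tol = 1e-12) {
  p <- params$dims$p; q <- params$dims$q; r <- params$dims$r
  df <- p + sum(params$dims$L)
  if (p > 1) df <- df + sum(abs(params$beta[upper.tri(params$beta)]) > zero_tol)
  for (j in seq_len(q))
    df <- df + sum(sqrt(rowSums(params$rho[[j]]^2)) > zero_tol) * params$dims$L[j]
  if (q > 1) for (j in seq_len(q - 1L)) for (k in (j + 1L):q)
    if (sqrt(sum(params$phi[[j]][[k]]^2)) > zero_tol)
      df <- df + length(params$phi[[j]][[k]])
  if (r > 0) {
    df <- df + sum(abs(params$gamma) > zero_tol)
    for (j in seq_len(q))
      df <- df + sum(sqrt(colSums(params$psi[[j]]^2)) > zero_tol) * params$dims$L[j]
  }
  df
}
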
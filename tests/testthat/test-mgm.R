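test_that("penalty terms follow the five-block arithmetic", {
  d <- make_null_dataset(30, 1)
  dims <- coxmgm:::mgm_dims(d)
  p0 <- coxmgm:::mgm_params_zero(dims)
  lam <- penalty_vector(2)
  expect_equal(coxmgm:::mgm_penalty(p0, lam), 0)

  # single nonzero rho_{s,j} = (3, 4, 0) with lambda_cd = 2: adds 2 * 5
  p1 <- p0
  p1$rho[[1]][1, ] <- c(3, 4, 0)
  lam_cd <- penalty_vector(c(0, 2, 0, 0, 0))
  expect_equal(coxmgm:::mgm_penalty(p1, lam_cd), 10)

  # all-ones phi block (3x3 here) with lambda_dd = 1: adds sqrt(9) = 3;
  # with a 2x2 block the Frobenius norm is 2
  p2 <- p0
  p2$phi[[1]][[2]][1:2, 1:2] <- 1
  p2$phi[[1]][[2]][3, ] <- 0; p2$phi[[1]][[2]][, 3] <- 0
  lam_dd <- penalty_vector(c(0, 0, 1, 0, 0))
  expect_equal(coxmgm:::mgm_penalty(p2, lam_dd), 2)

  # beta and gamma are lasso-penalized
  p3 <- p0
  p3$beta[1, 2] <- p3$beta[2, 1] <- -0.5
  p3$gamma[1, 1] <- 0.25
  lam_all <- penalty_vector(c(2, 0, 0, 4, 0))
  expect_equal(coxmgm:::mgm_penalty(p3, lam_all), 2 * 0.5 + 4 * 0.25)
  expect_error(penalty_vector(c(-1, 0, 0, 0, 0)), "negative penalty")
})

test_that("pseudolikelihood at zero interactions equals independent node fits", {
  d <- make_null_dataset(120, 7, n_cont = 2, n_disc = 2, n_cens = 1)
  ds <- coxmgm:::standardize_continuous(d)
  dims <- coxmgm:::mgm_dims(d)
  params <- coxmgm:::mgm_params_zero(dims)
  # intercepts at their conditional optima
  params$alpha <- colMeans(ds$continuous)
  for (j in 1:2)
    params$disc_int[[j]] <- log(as.numeric(table(ds$discrete[[j]])) / d$n)

  got <- negative_log_pseudolikelihood(params, d)

  # independent per-node oracles
  expect_gauss <- sum(vapply(1:2, function(s)
    -sum(dnorm(ds$continuous[, s], mean(ds$continuous[, s]), 1, log = TRUE)), 0))
  expect_multin <- sum(vapply(1:2, function(j) {
    ph <- as.numeric(table(ds$discrete[[j]])) / d$n
    -sum(log(ph[as.integer(ds$discrete[[j]])]))
  }, 0))
  cp0 <- cox_partial(d$time[, 1], d$event[, 1], rep(0, d$n), ties = "efron")
  expect_equal(got, expect_gauss + expect_multin - cp0$loglik, tolerance = 1e-8)
})

test_that("pseudolikelihood is additive over duplicated samples and local in beta", {
  # sample additivity holds exactly for the Gaussian and multinomial node
  # conditionals; the Cox partial likelihood couples samples through risk
  # sets, so the duplication check uses a censoring-free dataset
  dnc <- make_null_dataset(80, 15, n_cont = 2, n_disc = 2, n_cens = 0)
  dims_nc <- coxmgm:::mgm_dims(dnc)
  params_nc <- coxmgm:::mgm_params_zero(dims_nc)
  params_nc$beta[1, 2] <- params_nc$beta[2, 1] <- 0.3
  params_nc$rho[[1]][1, ] <- c(0.2, -0.1, -0.1)
  v1 <- negative_log_pseudolikelihood(params_nc, dnc, standardize = FALSE)
  ddup <- coxmgm:::dataset_subset(dnc, rep(seq_len(dnc$n), 2))
  v2 <- negative_log_pseudolikelihood(params_nc, ddup, standardize = FALSE)
  expect_equal(v2, 2 * v1, tolerance = 1e-8)

  d <- mgm_test_data(150)
  dims <- coxmgm:::mgm_dims(d)
  params <- coxmgm:::mgm_params_zero(dims)
  params$beta[1, 2] <- params$beta[2, 1] <- 0.3
  params$alpha <- c(0.1, -0.2)
  v1 <- negative_log_pseudolikelihood(params, d, standardize = FALSE)

  # perturbing beta_12 changes only the two continuous conditionals:
  # with discrete/censored conditionals untouched, the delta equals the
  # delta of the Gaussian part alone
  frame <- coxmgm:::mgm_frame(d, standardize = FALSE)
  gauss_part <- function(par) {
    fw <- coxmgm:::mgm_forward(par, frame)
    0.5 * sum((fw$mu - frame$X)^2)
  }
  params_b <- params
  params_b$beta[1, 2] <- params_b$beta[2, 1] <- 0.9
  delta_total <- negative_log_pseudolikelihood(params_b, d, standardize = FALSE) - v1
  delta_gauss <- gauss_part(params_b) - gauss_part(params)
  expect_equal(delta_total, delta_gauss, tolerance = 1e-10)
})

test_that("overwhelming penalties give an empty graph and objectives never increase", {
  d <- mgm_test_data(200)
  fit_big <- fit_coxmgm(d, 1e6)
  expect_equal(coxmgm:::n_edges(params_to_graph(fit_big)), 0)

  fit <- fit_coxmgm(d, 5, tol = 1e-6)
  expect_true(all(diff(fit$objective) <= 1e-9))
  expect_true(fit$converged)

  # penalized objective recomputed from parts matches the tracked value
  obj <- penalized_objective(fit$params, d, fit$penalties)
  expect_equal(obj, fit$objective[length(fit$objective)], tolerance = 1e-8)
})

test_that("the fitted graph recovers the generating structure of a 3-chain", {
  d <- mgm_test_data(400)
  # x1 - x2, x2 - y1, x1 - SURV are the generating edges
  fit <- fit_coxmgm(d, 25, tol = 1e-6)
  g <- params_to_graph(fit)
  expect_true(has_edge(g, "x1", "x2"))
  expect_true(has_edge(g, "x1", "SURV"))
})

test_that("continuous-only fits match a node-wise lasso oracle", {
  skip_if_not_installed("glmnet")
  set.seed(44)
  n <- 2000
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n); x3 <- 0.6 * x2 + rnorm(n)
  df <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  specs <- lapply(names(df), variable_spec, kind = "continuous")
  d <- validate_dataset(df, specs)
  lam <- 0.08                      # per-sample scale for glmnet
  # each shared beta appears in both endpoint conditionals, so the matching
  # penalty on the summed (unnormalized) objective is 2 * n * lam
  fit <- fit_coxmgm(d, 2 * lam * n, tol = 1e-8, max_iter = 3000)
  sel_mine <- params_to_graph(fit, zero_tol = 1e-4)

  Xs <- scale(as.matrix(df))
  sel_or <- matrix(FALSE, 3, 3)
  for (s in 1:3) {
    co <- as.numeric(coef(glmnet::glmnet(
      Xs[, -s], Xs[, s], lambda = lam, standardize = FALSE,
      thresh = 1e-12)))[-1]
    idx <- (1:3)[-s][abs(co) > 1e-4]
    sel_or[s, idx] <- TRUE
  }
  sel_or <- sel_or | t(sel_or)     # OR symmetrization
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(has_edge(sel_mine, i, j), sel_or[i, j],
                 info = paste("pair", i, j))
  # the chain pattern itself
  expect_true(has_edge(sel_mine, "x1", "x2"))
  expect_true(has_edge(sel_mine, "x2", "x3"))
  expect_false(has_edge(sel_mine, "x1", "x3"))
})

test_that("edge counts decrease monotonically along each penalty", {
  d <- mgm_test_data(250)
  base <- penalty_vector(8)
  for (ty in c("cc", "sc")) {
    counts <- vapply(c(2, 8, 30, 120, 500), function(l) {
      lam <- base; lam[ty] <- l
      coxmgm:::n_edges(params_to_graph(fit_coxmgm(d, lam, tol = 1e-5)))
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("params_to_graph thresholds block norms", {
  d <- make_null_dataset(30, 2, n_cont = 2, n_disc = 1, n_cens = 1)
  dims <- coxmgm:::mgm_dims(d)
  params <- coxmgm:::mgm_params_zero(dims)
  vn <- coxmgm:::dataset_var_names(d)
  kd <- coxmgm:::dataset_var_kinds(d)
  g0 <- params_to_graph(params, var_names = vn, kinds = kd)
  expect_equal(coxmgm:::n_edges(g0), 0)
  params$beta[1, 2] <- params$beta[2, 1] <- 0.5
  params$rho[[1]][1, ] <- 1e-12
  g1 <- params_to_graph(params, zero_tol = 1e-8, var_names = vn, kinds = kd)
  expect_equal(coxmgm:::n_edges(g1), 1)
  expect_true(has_edge(g1, "x1", "x2"))
})

test_that("Wz columns in the model frame equal the CI-test conditioning columns", {
  d <- make_null_dataset(100, 9, n_cens = 2)
  frame <- coxmgm:::mgm_frame(d)
  Zc <- expand_conditioning_set(c("S1", "S2"), d)
  expect_equal(unname(frame$M), unname(Zc), tolerance = 1e-10)
  wq <- cox_working_quantities(d$time[, 1], d$event[, 1], rep(0, d$n),
                               ties = "breslow")
  expect_equal(frame$M[, 1], wq$Wz, tolerance = 1e-8)
})

test_that("fitting requires events for every censored node", {
  d <- make_null_dataset(40, 3, n_cens = 1)
  d$event[, 1] <- 0
  expect_error(fit_coxmgm(d, 1), "zero observed events")
})
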
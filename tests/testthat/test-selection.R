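# A synthetic stability profile for rule-application tests.
fake_profile <- function(path, inst_matrix, pooled = NULL) {
  structure(list(path = path,
                 instability = inst_matrix,
                 pooled = if (is.null(pooled)) rowMeans(inst_matrix) else pooled,
                 B = 10L, b = 50L, seed = 1L),
            class = "stability_profile")
}

inst_mat <- function(v) matrix(rep(v, 5), ncol = 5,
                               dimnames = list(NULL, c("cc","cd","dd","sc","sd")))

test_that("the lambda path is log-even, decreasing, and empty at its head", {
  d <- make_null_dataset(150, 21, n_cens = 1)
  path <- build_lambda_path(d, K = 3, tol = 1e-4)
  expect_length(path, 3)
  expect_true(all(diff(path) < 0))
  ratios <- path[-1] / path[-length(path)]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-10)
  fit <- fit_coxmgm(d, path[1], tol = 1e-5)
  expect_equal(coxmgm:::n_edges(params_to_graph(fit)), 0)
  expect_equal(path[3], path[1] / 100, tolerance = 1e-8)
})

test_that("StEPS applies the monotonized-threshold rule per edge type", {
  path <- c(1.0, 0.5, 0.25, 0.125)
  prof <- fake_profile(path, inst_mat(c(0.01, 0.03, 0.06, 0.2)))
  lam <- steps_select(prof, threshold = 0.05)
  expect_equal(unname(lam), rep(0.5, 5))

  prof0 <- fake_profile(path, inst_mat(rep(0, 4)))
  expect_equal(unname(steps_select(prof0, 0.05)), rep(0.125, 5))

  # non-monotone dips after the crossing are ignored by the running maximum
  prof2 <- fake_profile(path, inst_mat(c(0.01, 0.06, 0.02, 0.2)))
  expect_equal(unname(steps_select(prof2, 0.05)), rep(1.0, 5))

  # no point satisfies the threshold: largest lambda, with a warning
  prof3 <- fake_profile(path, inst_mat(c(0.3, 0.3, 0.4, 0.45)))
  expect_warning(stars_select(prof3, 0.05), "largest lambda")
  lam3 <- suppressWarnings(steps_select(prof3, 0.05))
  expect_equal(unname(lam3), rep(1.0, 5))

  # per-type independence: sc curve crosses later than the others
  im <- inst_mat(c(0.01, 0.03, 0.06, 0.2))
  im[, "sc"] <- c(0.01, 0.06, 0.2, 0.3)
  prof4 <- fake_profile(path, im)
  lam4 <- steps_select(prof4, 0.05)
  expect_equal(unname(lam4["sc"]), 1.0)
  expect_equal(unname(lam4["cc"]), 0.5)
})

test_that("StARS pools all edge types into one selection", {
  path <- c(1.0, 0.5, 0.25)
  prof <- fake_profile(path, inst_mat(c(0.0, 0.04, 0.051)),
                       pooled = c(0.0, 0.04, 0.051))
  lam <- stars_select(prof, 0.05)
  expect_equal(unname(lam), rep(0.5, 3 + 2))
  expect_length(unique(lam), 1L)

  # identical per-type curves: StARS equals every StEPS component
  prof2 <- fake_profile(path, inst_mat(c(0.0, 0.04, 0.051)),
                        pooled = c(0.0, 0.04, 0.051))
  expect_equal(steps_select(prof2, 0.05), stars_select(prof2, 0.05))
})

test_that("instability arithmetic: always/half/never-selected edges", {
  # theta = 1 and theta = 0 contribute 0; theta = 0.5 contributes 0.5
  expect_equal(2 * 1 * (1 - 1), 0)
  freq <- c(1, 0.5, 0)
  expect_equal(2 * freq * (1 - freq), c(0, 0.5, 0))
  d <- make_null_dataset(400, 33, n_cens = 1)
  path <- build_lambda_path(d, K = 3, tol = 1e-4)
  prof <- stability_profile(d, path, B = 4, seed = 2, tol = 1e-4,
                            max_iter = 100L)
  # head of the path gives empty graphs in every subsample: instability 0
  expect_equal(unname(prof$instability[1, ]), rep(0, 5))
  expect_true(all(prof$instability >= 0 & prof$instability <= 0.5,
                  na.rm = TRUE))
  # deterministic given the seed, invariant to evaluation order
  prof2 <- stability_profile(d, path, B = 4, seed = 2, tol = 1e-4,
                             max_iter = 100L)
  expect_identical(prof$instability, prof2$instability)
  pth <- tempfile(fileext = ".json")
  write_stability_profile(prof, pth)
  expect_true(jsonlite::validate(paste(readLines(pth), collapse = "")))
})

test_that("StEPS keeps pure-noise graphs nearly empty", {
  edge_fracs <- vapply(1:6, function(s) {
    d <- make_null_dataset(500, 100 + s, n_cont = 3, n_disc = 2, n_cens = 1)
    path <- build_lambda_path(d, K = 6, tol = 1e-4)
    prof <- stability_profile(d, path, B = 6, seed = s, tol = 1e-4,
                              max_iter = 100L)
    lam <- steps_select(prof, 0.05)
    g <- params_to_graph(fit_coxmgm(d, lam, tol = 1e-5))
    coxmgm:::n_edges(g) / choose(6, 2)
  }, 0)
  expect_lte(median(edge_fracs), 0.05)
})

test_that("BIC prefers sparsity at equal fit and ignores forced zeros", {
  d <- mgm_test_data(300)
  dims <- coxmgm:::mgm_dims(d)
  p0 <- coxmgm:::mgm_params_zero(dims)
  p0$alpha <- colMeans(coxmgm:::standardize_continuous(d)$continuous)
  p1 <- p0
  p1$beta[1, 2] <- p1$beta[2, 1] <- 1e-30   # numerically zero-weight block
  # identical fit, fewer counted params for p0 is impossible here since the
  # perturbation is below support tolerance: BIC must be unchanged
  expect_equal(bic_score(d, p0), bic_score(d, p1))

  p2 <- p0
  p2$beta[1, 2] <- p2$beta[2, 1] <- 0.4
  # a parameter that genuinely improves fit lowers the deviance term
  expect_lt(2 * negative_log_pseudolikelihood(p2, d),
            2 * negative_log_pseudolikelihood(p0, d))
  # two models with the same deviance differ by the complexity penalty
  expect_equal(bic_score(d, p2) - 2 * negative_log_pseudolikelihood(p2, d) -
                 (bic_score(d, p0) - 2 * negative_log_pseudolikelihood(p0, d)),
               log(d$n) * 1)
})

test_that("BIC selects the empty model on independent data", {
  picks <- vapply(1:5, function(s) {
    d <- make_null_dataset(400, 200 + s, n_cont = 3, n_disc = 1, n_cens = 1)
    path <- build_lambda_path(d, K = 5, tol = 1e-4)
    sel <- bic_select(d, path, tol = 1e-4, max_iter = 150L)
    coxmgm:::n_edges(params_to_graph(sel$fits[[sel$best]]))
  }, 0)
  expect_lte(median(picks), 1)
})

test_that("StEPS matches or beats BIC on a small benchmark model", {
  # reduced-scale version of the stability-vs-BIC comparison
  f1s <- sapply(1:4, function(s) {
    cfg <- sim_config(12, "er", degree = 3, n_samples = 800,
                      censoring = "light", seed = 300 + s)
    m <- generate_dag(cfg)
    d <- simulate_mixed_data(m)$data
    tg <- truth_graph(m)
    path <- build_lambda_path(d, K = 6, tol = 1e-4)
    prof <- stability_profile(d, path, B = 6, seed = s, tol = 1e-4,
                              max_iter = 150L)
    g_steps <- params_to_graph(fit_coxmgm(d, steps_select(prof, 0.05),
                                          tol = 1e-5))
    sel <- bic_select(d, path, tol = 1e-4, max_iter = 150L)
    g_bic <- params_to_graph(sel$fits[[sel$best]])
    c(steps = adjacency_confusion(g_steps, tg)$f1,
      bic = adjacency_confusion(g_bic, tg)$f1)
  })
  expect_gte(median(f1s["steps", ]), median(f1s["bic", ]) - 0.02)
})
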
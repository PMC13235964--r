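#' Configuration for the benchmark simulator
#'
#' Describes a ground-truth causal model over mixed-type nodes: graph
#' topology (Erdos-Renyi or scale-free), average node degree, the proportions
#' of continuous / discrete / censored nodes, sample size, and the censoring
#' condition (`"light"` = 30% censored, `"heavy"` = 70% censored, `"none"`).
#'
#' @param n_nodes Number of nodes.
#' @param topology `"er"` or `"sf"`.
#' @param degree Average node degree (so `floor(n_nodes*degree/2)` edges).
#' @param type_fractions Length-3 numeric (continuous, discrete, censored)
#'   summing to 1. Default `c(5, 5, 1)/11`.
#' @param n_samples Samples to draw.
#' @param censoring `"light"`, `"heavy"`, or `"none"`.
#' @param coef_range Magnitude range for edge coefficients (random sign).
#' @param n_levels Level count for discrete nodes.
#' @param weibull_shape Shape of the Weibull baseline hazard for censored
#'   nodes (default 1.5, increasing hazard).
#' @param seed Integer seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_nodes, topology = c("er", "sf"), degree = 4,
                       type_fractions = c(5, 5, 1) / 11,
                       n_samples = 500,
                       censoring = c("light", "heavy", "none"),
                       coef_range = c(0.3, 1.0),
                       n_levels = 3L,
                       weibull_shape = 1.5,
                       seed = 1L) {
  topology <- match.arg(topology)
  censoring <- match.arg(censoring)
  stopifnot(degree < n_nodes, abs(sum(type_fractions) - 1) < 1e-8,
            n_samples >= 1, coef_range[1] > 0, coef_range[2] >= coef_range[1])
  n_edges <- floor(n_nodes * degree / 2)
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("requested edges exceed N(N-1)/2")
  structure(list(n_nodes = n_nodes, topology = topology, degree = degree,
                 type_fractions = type_fractions, n_samples = n_samples,
                 censoring = censoring, coef_range = coef_range,
                 n_levels = as.integer(n_levels),
                 weibull_shape = weibull_shape, seed = as.integer(seed)),
            class = "sim_config")
}

## Largest-remainder allocation of N into counts proportional to fractions.
allocate_types <- function(N, fractions) {
  base <- floor(fractions * N)
  rem <- N - sum(base)
  if (rem > 0) {
    frac <- fractions * N - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Generate a ground-truth DAG with typed nodes and edge coefficients
#'
#' ER topology places exactly `floor(N*degree/2)` edges uniformly among node
#' pairs and orients them along a random topological order; SF topology grows
#' a preferential-attachment skeleton with the same edge count, oriented from
#' older to newer nodes. Node types are assigned uniformly at random in the
#' configured proportions; every edge receives a coefficient drawn uniformly
#' from plus-or-minus `coef_range`.
#'
#' @param config A [sim_config()].
#' @return An object of class `"ground_truth_model"` with the adjacency
#'   matrix `amat` (`amat[i, j] = 1` means an edge i -> j), node `kinds`,
#'   `levels` per discrete node, edge `weights` (same shape as `amat`), the
#'   topological `order`, and the generating `config`.
#' @export
generate_dag <- function(config) {
  set.seed(config$seed)
  N <- config$n_nodes
  n_edges <- floor(N * config$degree / 2)

  amat <- matrix(0L, N, N)
  if (config$topology == "er") {
    topo <- sample.int(N)                  # topo[k] = node in position k
    pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    pos <- integer(N); pos[topo] <- seq_len(N)
    for (i in seq_len(nrow(sel))) {
      a <- sel[i, 1L]; b <- sel[i, 2L]
      if (pos[a] < pos[b]) amat[a, b] <- 1L else amat[b, a] <- 1L
    }
    order_out <- topo
  } else {
    ## preferential attachment with m = degree/2 edges per incoming node,
    ## topped up / trimmed to exactly n_edges; orientation: older -> newer.
    m <- max(1L, round(config$degree / 2))
    deg <- rep(0L, N)
    edges <- matrix(0L, 0, 2)
    for (v in 2:N) {
      k <- min(m, v - 1L)
      w <- deg[seq_len(v - 1L)] + 1
      tgt <- sample.int(v - 1L, size = k, prob = w / sum(w))
      for (u in tgt) {
        edges <- rbind(edges, c(u, v))
        deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      }
    }
    if (nrow(edges) > n_edges) {
      edges <- edges[sample.int(nrow(edges), n_edges), , drop = FALSE]
    } else while (nrow(edges) < n_edges) {
      v <- sample(2:N, 1L)
      w <- deg[seq_len(v - 1L)] + 1
      u <- sample.int(v - 1L, 1L, prob = w / sum(w))
      dup <- any(edges[, 1L] == u & edges[, 2L] == v)
      if (!dup) {
        edges <- rbind(edges, c(u, v))
        deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      }
    }
    amat[edges] <- 1L
    order_out <- seq_len(N)
  }

  counts <- allocate_types(N, config$type_fractions)
  kinds <- rep(c("continuous", "discrete", "censored"), counts)
  kinds <- sample(kinds)
  names(kinds) <- node_names_for(kinds)
  dimnames(amat) <- list(names(kinds), names(kinds))

  weights <- matrix(0, N, N, dimnames = dimnames(amat))
  idx <- which(amat == 1L)
  weights[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
    stats::runif(length(idx), config$coef_range[1], config$coef_range[2])

  ## per discrete PARENT node: level contributions (one weight per level,
  ## centered), scaled by the edge weight at use time
  level_scores <- lapply(seq_len(N), function(i) {
    if (kinds[i] == "discrete") {
      s <- stats::rnorm(config$n_levels)
      s - mean(s)
    } else NULL
  })

  structure(list(amat = amat, kinds = kinds, weights = weights,
                 level_scores = level_scores,
                 order = topological_order(amat),
                 config = config, seed = config$seed),
            class = "ground_truth_model")
}

node_names_for <- function(kinds) {
  counters <- c(continuous = 0L, discrete = 0L, censored = 0L)
  prefix <- c(continuous = "X", discrete = "Y", censored = "S")
  vapply(kinds, function(k) {
    counters[k] <<- counters[k] + 1L
    paste0(prefix[k], counters[k])
  }, "")
}

## Topological order of a DAG adjacency matrix (i->j when amat[i,j]==1).
topological_order <- function(amat) {
  N <- nrow(amat)
  indeg <- colSums(amat)
  out <- integer(0)
  avail <- which(indeg == 0)
  indeg_w <- indeg
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    ch <- which(amat[v, ] == 1L)
    for (c in ch) {
      indeg_w[c] <- indeg_w[c] - 1L
      if (indeg_w[c] == 0L) avail <- c(avail, c)
    }
  }
  if (length(out) != N) stop("graph is not acyclic")
  out
}

#' Calibrate an exponential censoring rate to a target censored fraction
#'
#' Given a sample of latent event times, finds by bisection the exponential
#' rate `c` such that the expected censored fraction
#' `mean(1 - exp(-c * T))` equals `target`. The event-time sample plays the
#' role of the Monte-Carlo draw; the solution is deterministic given it.
#'
#' @param event_times Latent (uncensored) event-time sample.
#' @param target Target censored fraction in (0, 1).
#' @param tol Bisection tolerance on the achieved fraction.
#' @return The censoring rate (scalar).
#' @export
calibrate_censoring <- function(event_times, target, tol = 1e-6) {
  stopifnot(target > 0, target < 1, all(event_times >= 0))
  frac <- function(c) mean(1 - exp(-c * event_times))
  lo <- 1e-12; hi <- 1
  it <- 0L
  while (frac(hi) < target) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 200L) stop("censoring calibration did not converge")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (abs(frac(mid) - target) < tol) break
  }
  (lo + hi) / 2
}

#' Draw a mixed-type dataset from a ground-truth model
#'
#' Ancestral sampling in topological order: continuous children are linear in
#' parent contributions with unit Gaussian noise; discrete children are
#' multinomial-logistic in the scalar parent contribution (level scores
#' spread the effect over levels); censored children draw an event time from
#' a Weibull proportional-hazards model whose linear predictor is the parent
#' contribution, with an independent exponential censoring time whose rate is
#' calibrated so the expected censored fraction matches the condition (30%
#' light, 70% heavy). The recorded value is `(min(T, C), 1[T <= C])`.
#'
#' @param model A [generate_dag()] result.
#' @param n_samples Number of samples (defaults to the config value).
#' @param censoring Censoring condition (defaults to the config value).
#' @param seed Seed for the draw (defaults to `model$seed + 1`).
#' @return A list with `data` (a `mixed_dataset`), `latent` (matrix of
#'   pre-censoring node values), and `model`.
#' @export
simulate_mixed_data <- function(model, n_samples = NULL, censoring = NULL,
                                seed = NULL) {
  config <- model$config
  if (is.null(n_samples)) n_samples <- config$n_samples
  if (is.null(censoring)) censoring <- config$censoring
  if (!censoring %in% c("light", "heavy", "none"))
    stop("unknown censoring condition: ", censoring)
  if (is.null(seed)) seed <- model$seed + 1L
  set.seed(seed)
  target <- switch(censoring, light = 0.30, heavy = 0.70, none = NA_real_)

  N <- config$n_nodes; n <- n_samples
  kinds <- model$kinds
  contrib <- matrix(0, n, N)      # standardized contribution of each node
  valmat <- matrix(0, n, N)       # raw node values (latent for censored)
  disc_vals <- vector("list", N)
  time_m <- list(); event_m <- list()

  for (v in model$order) {
    pa <- which(model$amat[, v] == 1L)
    eta <- rep(0, n)
    for (u in pa) eta <- eta + model$weights[u, v] * contrib[, u]
    if (kinds[v] == "continuous") {
      x <- eta + stats::rnorm(n)
      valmat[, v] <- x
      contrib[, v] <- x
    } else if (kinds[v] == "discrete") {
      L <- config$n_levels
      s <- seq(-1, 1, length.out = L)        # level loadings of eta
      logits <- outer(eta, s)                # n x L
      pr <- exp(logits - apply(logits, 1, max))
      pr <- pr / rowSums(pr)
      u <- stats::runif(n)
      cp <- t(apply(pr, 1L, cumsum))
      yv <- rowSums(u > cp) + 1L
      disc_vals[[v]] <- factor(paste0("l", yv), levels = paste0("l", 1:L))
      sc <- model$level_scores[[v]][yv]
      contrib[, v] <- (sc - mean(sc)) / max(stats::sd(sc), 1e-8)
      valmat[, v] <- yv
    } else {
      shape <- config$weibull_shape
      Tlat <- (-log(stats::runif(n)) / exp(eta))^(1 / shape)
      valmat[, v] <- Tlat
      lt <- log(Tlat)
      contrib[, v] <- (lt - mean(lt)) / max(stats::sd(lt), 1e-8)
      if (censoring == "none") {
        time_m[[names(kinds)[v]]] <- Tlat
        event_m[[names(kinds)[v]]] <- rep(1, n)
      } else {
        rate <- calibrate_censoring(Tlat, target)
        C <- stats::rexp(n, rate)
        time_m[[names(kinds)[v]]] <- pmin(Tlat, C)
        event_m[[names(kinds)[v]]] <- as.numeric(Tlat <= C)
      }
    }
  }

  cont_idx <- which(kinds == "continuous")
  disc_idx <- which(kinds == "discrete")
  cens_idx <- which(kinds == "censored")

  continuous <- valmat[, cont_idx, drop = FALSE]
  colnames(continuous) <- names(kinds)[cont_idx]
  discrete <- as.data.frame(disc_vals[disc_idx],
                            col.names = names(kinds)[disc_idx])
  if (length(disc_idx) == 0L) discrete <- as.data.frame(matrix(nrow = n, ncol = 0))
  tm <- do.call(cbind, time_m[names(kinds)[cens_idx]])
  ev <- do.call(cbind, event_m[names(kinds)[cens_idx]])
  if (is.null(tm)) { tm <- matrix(0, n, 0); ev <- matrix(0, n, 0) }

  specs <- c(
    lapply(names(kinds)[cont_idx], variable_spec, kind = "continuous"),
    lapply(names(kinds)[disc_idx], function(nm)
      variable_spec(nm, "discrete", levels = paste0("l", 1:config$n_levels))),
    lapply(names(kinds)[cens_idx], function(nm)
      variable_spec(nm, "censored", time_col = paste0(nm, "_time"),
                    event_col = paste0(nm, "_event")))
  )

  data <- structure(list(sample_ids = as.character(seq_len(n)),
                         continuous = continuous, discrete = discrete,
                         time = tm, event = ev, specs = specs,
                         n = n, p = length(cont_idx), q = length(disc_idx),
                         r = length(cens_idx), dropped = 0L),
                    class = "mixed_dataset")
  list(data = data, latent = valmat, model = model)
}

#' Flatten a mixed dataset to a plain data.frame (censored pairs expanded)
#' @param data A `mixed_dataset`.
#' @return data.frame with continuous, discrete, and `_time`/`_event` columns.
#' @export
dataset_to_table <- function(data) {
  out <- as.data.frame(data$continuous)
  for (nm in names(data$discrete)) out[[nm]] <- as.character(data$discrete[[nm]])
  cens_specs <- Filter(function(s) s$kind == "censored", data$specs)
  names(cens_specs) <- vapply(cens_specs, `[[`, "", "name")
  for (nm in colnames(data$time)) {
    sp <- cens_specs[[nm]]
    tc <- if (!is.null(sp)) sp$time_col else paste0(nm, "_time")
    ec <- if (!is.null(sp)) sp$event_col else paste0(nm, "_event")
    out[[tc]] <- data$time[, nm]
    out[[ec]] <- data$event[, nm]
  }
  if (ncol(out) == 0L) out <- data.frame(row.names = seq_len(data$n))
  out
}

#' Ground-truth model as an endpoint graph (DAG)
#' @param model A [generate_dag()] result.
#' @return An `endpoint_graph` tagged `"dag"`.
#' @export
truth_graph <- function(model) {
  g <- endpoint_graph(names(model$kinds), kinds = model$kinds, gclass = "dag")
  idx <- which(model$amat == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    g <- add_edge(g, idx[i, 1L], idx[i, 2L], "t", "a")
  }
  g
}
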
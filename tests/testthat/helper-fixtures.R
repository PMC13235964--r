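# Shared fixtures: all test inputs are generated in code.

# Small mixed table (2 continuous, 2 discrete, 2 censored pairs), mutually
# independent unless stated otherwise.
make_null_table <- function(n, seed, n_cont = 2L, n_disc = 2L, n_cens = 2L,
                            cens_rate = 0.5) {
  set.seed(seed)
  df <- data.frame(row.names = seq_len(n))
  for (i in seq_len(n_cont)) df[[paste0("x", i)]] <- rnorm(n)
  for (i in seq_len(n_disc))
    df[[paste0("y", i)]] <- sample(c("a", "b", "c"), n, replace = TRUE)
  for (i in seq_len(n_cens)) {
    tt <- rexp(n)
    cc <- rexp(n, cens_rate)
    df[[paste0("s", i, "_t")]] <- pmin(tt, cc)
    df[[paste0("s", i, "_e")]] <- as.numeric(tt <= cc)
  }
  df
}

make_null_specs <- function(n_cont = 2L, n_disc = 2L, n_cens = 2L) {
  c(lapply(seq_len(n_cont), function(i)
      variable_spec(paste0("x", i), "continuous")),
    lapply(seq_len(n_disc), function(i)
      variable_spec(paste0("y", i), "discrete", levels = c("a", "b", "c"))),
    lapply(seq_len(n_cens), function(i)
      variable_spec(paste0("S", i), "censored",
                    time_col = paste0("s", i, "_t"),
                    event_col = paste0("s", i, "_e"))))
}

make_null_dataset <- function(n, seed, ...) {
  suppressMessages(validate_dataset(make_null_table(n, seed, ...),
                                    make_null_specs(...)))
}

# DAG constructors ----------------------------------------------------------

make_dag <- function(nodes, edges, kinds = NULL) {
  g <- endpoint_graph(nodes, kinds = kinds, gclass = "dag")
  for (e in edges) g <- add_edge(g, e[1], e[2], "t", "a")
  g
}

complete_skeleton <- function(nodes) {
  g <- endpoint_graph(nodes)
  for (i in seq_along(nodes)[-length(nodes)])
    for (j in (i + 1):length(nodes)) g <- add_edge(g, nodes[i], nodes[j])
  g
}

# All DAG adjacency matrices on k labeled nodes (k <= 4 recommended).
enumerate_dags <- function(k, max_edges = Inf) {
  cells <- which(diag(k) == 0)
  out <- list()
  for (code in 0:(2^(k * (k - 1)) - 1)) {
    A <- matrix(0L, k, k)
    A[cells] <- as.integer(intToBits(code)[seq_along(cells)])
    if (sum(A) > max_edges) next
    ok <- tryCatch({ coxmgm:::topological_order(A); TRUE },
                   error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- A
  }
  out
}

random_sparse_dag <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  repeat {
    A <- matrix(0L, n_nodes, n_nodes)
    perm <- sample.int(n_nodes)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    pos <- integer(n_nodes); pos[perm] <- seq_len(n_nodes)
    for (i in seq_len(nrow(sel))) {
      a <- sel[i, 1]; b <- sel[i, 2]
      if (pos[a] < pos[b]) A[a, b] <- 1L else A[b, a] <- 1L
    }
    return(A)
  }
}

named_amat <- function(A, prefix = "V") {
  dimnames(A) <- list(paste0(prefix, seq_len(nrow(A))),
                      paste0(prefix, seq_len(nrow(A))))
  A
}

# positional mark-string key for graph equality in partitions
graph_key <- function(g) paste(ifelse(g$marks == "", ".", g$marks),
                               collapse = "")

# proportional-hazards survival draw: h(t) = shape * t^(shape-1) * exp(eta)
draw_weibull_ph <- function(eta, shape = 1.5) {
  (-log(runif(length(eta))) / exp(eta))^(1 / shape)
}

# A small correlated mixed dataset shared by fitting tests:
# x1 - x2, x2 - y1, x1 - SURV are the generating associations.
mgm_test_data <- function(n = 400, seed = 101) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n)
  y1 <- factor(ifelse(x2 + rnorm(n) > 0, "a", ifelse(rnorm(n) > 0, "b", "c")),
               levels = c("a", "b", "c"))
  eta <- 0.7 * x1
  tt <- draw_weibull_ph(eta)
  cc <- rexp(n, calibrate_censoring(tt, 0.3))
  df <- data.frame(x1 = x1, x2 = x2, y1 = y1,
                   s_t = pmin(tt, cc), s_e = as.numeric(tt <= cc))
  specs <- list(variable_spec("x1", "continuous"),
                variable_spec("x2", "continuous"),
                variable_spec("y1", "discrete", levels = c("a", "b", "c")),
                variable_spec("SURV", "censored", time_col = "s_t",
                              event_col = "s_e"))
  validate_dataset(df, specs)
}
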
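## Constraint-based orientation of CoxMGM skeletons: PC-Stable adjacency
## pruning, majority-rule collider orientation (MPC-Stable), Meek closure,
## and FCI with PAG output.
##
## Endpoint-mark convention (see graph.R): marks[i, j] is the mark at node j
## on edge i ~ j. A directed edge a -> b has marks[a, b] = "a" (arrow at b)
## and marks[b, a] = "t" (tail at a).

#' Build a data-driven conditional-independence tester with caching
#'
#' Returns a function `(x, y, S) -> p-value` wrapping [ci_test()]; p-values
#' are cached keyed by the unordered pair and the conditioning set, so
#' majority voting and alpha sweeps re-use results.
#'
#' @param data A `mixed_dataset`.
#' @param config A [ci_config()].
#' @return A tester closure with attribute `"cache"` (an environment).
#' @export
ci_tester <- function(data, config = ci_config()) {
  cache <- new.env(parent = emptyenv())
  expn <- new.env(parent = emptyenv())   # per-variable expansion columns
  f <- function(x, y, S = character(0)) {
    pr <- sort(c(x, y))
    key <- paste(pr[1L], pr[2L], paste(sort(S), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- ci_test(pr[1L], pr[2L], S, data, config, cache = expn)$p_value
    cache[[key]] <- p
    p
  }
  attr(f, "cache") <- cache
  f
}

#' d-separation oracle tester for a known DAG
#'
#' Returns a tester `(x, y, S) -> p` with p = 1 when `x` and `y` are
#' d-separated given `S` in the DAG and p = 0 otherwise. With latent nodes
#' declared, queries over the observed nodes answer m-separation on the
#' latent projection (d-separation in the full DAG given observed S).
#'
#' @param truth An `endpoint_graph` tagged `"dag"`, or an adjacency matrix
#'   (`A[i,j] = 1` for i -> j).
#' @return A tester closure.
#' @export
oracle_tester <- function(truth) {
  A <- if (inherits(truth, "endpoint_graph")) dag_amat(truth) else truth
  nodes <- rownames(A)
  function(x, y, S = character(0)) {
    xi <- match(x, nodes); yi <- match(y, nodes)
    Si <- match(S, nodes)
    if (anyNA(c(xi, yi, Si))) stop("unknown node in oracle query")
    if (dsep(A, xi, yi, Si)) 1 else 0
  }
}

subsets_of <- function(v, d) {
  if (d == 0L) return(list(character(0)))
  if (length(v) < d) return(list())
  utils::combn(v, d, simplify = FALSE)
}

#' PC-Stable skeleton search
#'
#' Order-independent edge removal: at each depth d the adjacency sets are
#' frozen, and an edge (X, Y) is removed if some size-d subset S of
#' adj(X)\\{Y} or adj(Y)\\{X} yields p > alpha. Separating sets are
#' recorded with their p-values. A failing test (error) conservatively
#' retains the edge with a warning.
#'
#' @param init An undirected `endpoint_graph` (the starting adjacencies,
#'   e.g. a CoxMGM skeleton or a complete graph).
#' @param tester A tester function `(x, y, S) -> p` ([ci_tester()] or
#'   [oracle_tester()]).
#' @param alpha Significance level.
#' @param max_depth Maximum conditioning-set size.
#' @return List with `graph` (pruned skeleton) and `sepsets` (environment
#'   mapping `"A|B"` pair keys to lists of records `list(S, p)`).
#' @export
pc_stable_skeleton <- function(init, tester, alpha = 0.05, max_depth = 3L) {
  g <- init
  g$gclass <- "skeleton"
  g$marks[g$marks != ""] <- "t"
  sepsets <- new.env(parent = emptyenv())
  nodes <- g$nodes
  for (d in 0:max_depth) {
    adj_frozen <- lapply(seq_along(nodes), function(i) nodes[adj_of(g, i)])
    e <- graph_edges(g)
    if (!nrow(e)) break
    any_candidate <- FALSE
    for (k in seq_len(nrow(e))) {
      x <- e$a[k]; y <- e$b[k]
      if (!has_edge(g, x, y)) next
      cands <- unique(c(subsets_of(setdiff(adj_frozen[[match(x, nodes)]], y), d),
                        subsets_of(setdiff(adj_frozen[[match(y, nodes)]], x), d)))
      if (length(cands)) any_candidate <- TRUE
      for (S in cands) {
        p <- tryCatch(tester(x, y, S), error = function(err) {
          warning("CI test failed for (", x, ", ", y, " | ",
                  paste(S, collapse = ","), "): ", conditionMessage(err),
                  "; edge retained")
          NA_real_
        })
        if (!is.na(p) && p > alpha) {
          g <- remove_edge(g, x, y)
          key <- paste(sort(c(x, y)), collapse = "|")
          sepsets[[key]] <- c(sepsets[[key]], list(list(S = S, p = p)))
          break
        }
      }
    }
    if (!any_candidate && d > 0L) break
  }
  list(graph = g, sepsets = sepsets)
}

## All separating subsets (sizes 0..max_depth, deduplicated) for pair
## (x, y) within the frozen adjacency sets of a skeleton.
collect_sepsets <- function(g, x, y, tester, alpha, max_depth) {
  nodes <- g$nodes
  ax <- setdiff(nodes[adj_of(g, x)], y)
  ay <- setdiff(nodes[adj_of(g, y)], x)
  seen <- character(0)
  out <- list()
  for (d in 0:max_depth) {
    for (side in list(ax, ay)) {
      for (S in subsets_of(side, d)) {
        key <- paste(sort(S), collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        p <- tryCatch(tester(x, y, S), error = function(err) NA_real_)
        if (!is.na(p) && p > alpha) out <- c(out, list(S))
      }
    }
  }
  out
}

#' Majority-rule collider orientation (MPC-Stable)
#'
#' For each unshielded triple X - Z - Y, collects all separating subsets of
#' the adjacency sets of X and Y; the triple is oriented as a collider
#' X -> Z <- Y iff Z appears in a minority (< 50%) of the separating sets,
#' left untouched when exactly 50% (logged as ambiguous), and treated as a
#' non-collider otherwise.
#'
#' @param skeleton Undirected `endpoint_graph` from [pc_stable_skeleton()].
#' @param tester Tester function.
#' @param alpha Significance level.
#' @param max_depth Maximum conditioning-set size.
#' @param circles If `TRUE`, non-arrow endpoints keep circle marks (FCI
#'   usage); otherwise tails (CPDAG usage).
#' @return An `endpoint_graph` with colliders oriented.
#' @export
orient_colliders_majority <- function(skeleton, tester, alpha = 0.05,
                                      max_depth = 3L, circles = FALSE) {
  g <- skeleton
  g$marks[g$marks != ""] <- if (circles) "c" else "t"
  g$gclass <- if (circles) "pag" else "cpdag"
  nodes <- g$nodes
  for (z in seq_along(nodes)) {
    nb <- adj_of(skeleton, z)
    if (length(nb) < 2L) next
    for (ii in seq_along(nb)) for (jj in seq_along(nb)) {
      if (ii >= jj) next
      x <- nb[ii]; y <- nb[jj]
      if (has_edge(skeleton, x, y)) next
      seps <- collect_sepsets(skeleton, nodes[x], nodes[y], tester, alpha,
                              max_depth)
      if (!length(seps)) {
        warning("no separating set found for nonadjacent pair (",
                nodes[x], ", ", nodes[y], "); triple skipped")
        next
      }
      frac <- mean(vapply(seps, function(S) nodes[z] %in% S, TRUE))
      if (frac < 0.5) {
        g$marks[x, z] <- "a"
        g$marks[y, z] <- "a"
      } else if (frac == 0.5) {
        message("ambiguous triple (", nodes[x], ", ", nodes[z], ", ",
                nodes[y], "): in exactly half of separating sets")
      }
    }
  }
  g
}

#' MPC-Stable: majority-rule PC on an initial skeleton
#'
#' PC-Stable pruning, majority-rule collider orientation, then Meek closure
#' to a CPDAG.
#'
#' @inheritParams pc_stable_skeleton
#' @return An `endpoint_graph` tagged `"cpdag"`.
#' @export
mpc_stable <- function(init, tester, alpha = 0.05, max_depth = 3L) {
  sk <- pc_stable_skeleton(init, tester, alpha, max_depth)
  g <- orient_colliders_majority(sk$graph, tester, alpha, max_depth,
                                 circles = FALSE)
  g <- meek_closure(g)
  g$gclass <- "cpdag"
  g
}

## ---- FCI ------------------------------------------------------------------

## Possible-D-SEP(x): nodes reachable from x along a path on which every
## intermediate vertex is a collider or lies in a triangle with its path
## neighbours.
possible_dsep <- function(g, x) {
  N <- length(g$nodes)
  xi <- node_index(g, x)
  seen <- matrix(FALSE, N, N)
  out <- logical(N)
  frontier <- lapply(adj_of(g, xi), function(v) c(xi, v))
  for (f in frontier) seen[f[1L], f[2L]] <- TRUE
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      prev <- st[1L]; cur <- st[2L]
      out[cur] <- TRUE
      for (nb in adj_of(g, cur)) {
        if (nb == prev) next
        collider <- g$marks[prev, cur] == "a" && g$marks[nb, cur] == "a"
        triangle <- g$marks[prev, nb] != ""
        if ((collider || triangle) && !seen[cur, nb]) {
          seen[cur, nb] <- TRUE
          nxt <- c(nxt, list(c(cur, nb)))
        }
      }
    }
    frontier <- nxt
  }
  out[xi] <- FALSE
  g$nodes[out]
}

## Potentially-directed edge a *-* b traversable a -> b: mark at a is not an
## arrow and mark at b is not a tail.
is_pd_edge <- function(g, a, b) {
  g$marks[b, a] != "a" && g$marks[a, b] != "t"
}

## First intermediate vertices of uncovered potentially-directed paths from
## a to target (the target itself when the direct edge qualifies).
ucp_first_vertices <- function(g, a, target, limit = 20000L) {
  firsts <- integer(0)
  count <- 0L
  recurse <- function(path) {
    if (count > limit) return()
    cur <- path[length(path)]
    for (nb in adj_of(g, cur)) {
      if (nb %in% path) next
      if (!is_pd_edge(g, cur, nb)) next
      if (length(path) >= 2L) {
        pre <- path[length(path) - 1L]
        if (g$marks[pre, nb] != "") next      # covered triple
      }
      count <<- count + 1L
      if (nb == target) {
        first <- if (length(path) >= 2L) path[2L] else nb
        firsts <<- union(firsts, first)
      } else recurse(c(path, nb))
    }
  }
  recurse(a)
  firsts
}

## Discriminating-path search: given a *-> b (arrow at b), a -> c, walk
## backwards over colliders that are parents of c; returns the index of a
## vertex d nonadjacent to c closing a discriminating path for b, or NULL.
dpath_search <- function(g, a, b, c) {
  visited <- c(a, b, c)
  frontier <- a
  while (length(frontier)) {
    nxt <- integer(0)
    for (cur in frontier) {
      for (d in adj_of(g, cur)) {
        if (d %in% visited) next
        if (g$marks[d, cur] != "a") next          # need arrow at cur from d
        if (g$marks[d, c] == "") return(d)        # d nonadjacent to c: found
        ## to extend, d must be a collider candidate (arrow at d from cur)
        ## and a parent of c
        if (g$marks[cur, d] == "a" &&
            g$marks[d, c] == "a" && g$marks[c, d] == "t") {
          visited <- c(visited, d)
          nxt <- c(nxt, d)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

## Zhang's orientation rules R1-R4 and R8-R10 to fixpoint. The
## selection-bias rules R5-R7 cannot fire under the package's
## no-selection-bias assumption and are omitted. `sep_lookup(d, c, b)`
## answers whether b lies in (the majority of) separating sets of (d, c).
zhang_closure <- function(g, sep_lookup = NULL) {
  N <- length(g$nodes)
  repeat {
    changed <- FALSE
    ## R1: a *-> b o-* c (circle at b on b~c), a,c nonadjacent => b -> c
    for (b in seq_len(N)) for (c in seq_len(N)) {
      if (b == c || g$marks[c, b] != "c") next
      for (a in seq_len(N)) {
        if (a %in% c(b, c) || g$marks[a, b] != "a") next
        if (g$marks[a, c] == "") {
          g$marks[c, b] <- "t"
          g$marks[b, c] <- "a"
          changed <- TRUE
          break
        }
      }
    }
    ## R2: (a -> b *-> c) or (a *-> b -> c), circle at c on a~c => a *-> c
    for (a in seq_len(N)) for (c in seq_len(N)) {
      if (a == c || g$marks[a, c] != "c") next
      for (b in seq_len(N)) {
        if (b %in% c(a, c) || g$marks[a, b] == "") next
        chain1 <- g$marks[a, b] == "a" && g$marks[b, a] == "t" &&
          g$marks[b, c] == "a"
        chain2 <- g$marks[a, b] == "a" &&
          g$marks[b, c] == "a" && g$marks[c, b] == "t"
        if (chain1 || chain2) {
          g$marks[a, c] <- "a"
          changed <- TRUE
          break
        }
      }
    }
    ## R3: a *-> b <-* c, a *-o d o-* c, a,c nonadjacent, d *-o b => d *-> b
    for (d in seq_len(N)) for (b in seq_len(N)) {
      if (d == b || g$marks[d, b] != "c") next
      hit <- FALSE
      for (a in seq_len(N)) {
        if (hit) break
        if (a %in% c(d, b)) next
        for (c in seq_len(N)) {
          if (c %in% c(d, b, a)) next
          if (g$marks[a, b] == "a" && g$marks[c, b] == "a" &&
              g$marks[a, d] == "c" && g$marks[c, d] == "c" &&
              g$marks[a, c] == "" && g$marks[c, a] == "") { hit <- TRUE; break }
        }
      }
      if (hit) { g$marks[d, b] <- "a"; changed <- TRUE }
    }
    ## R4: discriminating path <d, ..., a, b, c> for b
    for (b in seq_len(N)) for (c in seq_len(N)) {
      if (b == c || g$marks[b, c] == "") next
      if (g$marks[c, b] != "c") next              # circle at b on b~c
      for (a in seq_len(N)) {
        if (a %in% c(b, c)) next
        if (!(g$marks[a, c] == "a" && g$marks[c, a] == "t")) next   # a -> c
        if (g$marks[b, a] != "a") next            # arrow at a from b side
        if (g$marks[a, b] == "") next
        d <- dpath_search(g, a, b, c)
        if (!is.null(d) && !is.null(sep_lookup)) {
          dec <- sep_lookup(g$nodes[d], g$nodes[c], g$nodes[b])
          if (isTRUE(dec)) {
            g$marks[c, b] <- "t"; g$marks[b, c] <- "a"
          } else if (isFALSE(dec)) {
            g$marks[a, b] <- "a"; g$marks[b, a] <- "a"
            g$marks[b, c] <- "a"; g$marks[c, b] <- "a"
          }
          if (!is.na(dec)) { changed <- TRUE; break }
        }
      }
    }
    ## R8: a -> b -> c or a -o b -> c, with a o-> c => a -> c
    for (a in seq_len(N)) for (c in seq_len(N)) {
      if (a == c || !(g$marks[c, a] == "c" && g$marks[a, c] == "a")) next
      for (b in seq_len(N)) {
        if (b %in% c(a, c)) next
        ab <- (g$marks[a, b] == "a" || g$marks[a, b] == "c") &&
          g$marks[b, a] == "t"
        bc <- g$marks[b, c] == "a" && g$marks[c, b] == "t"
        if (ab && bc) { g$marks[c, a] <- "t"; changed <- TRUE; break }
      }
    }
    ## R9: a o-> c, uncovered p.d. path <a, b, ..., c>, b,c nonadjacent
    ##     => a -> c
    for (a in seq_len(N)) for (c in seq_len(N)) {
      if (a == c || !(g$marks[c, a] == "c" && g$marks[a, c] == "a")) next
      firsts <- ucp_first_vertices(g, a, c)
      firsts <- setdiff(firsts, c)
      if (any(vapply(firsts, function(b) g$marks[b, c] == "" &&
                     g$marks[c, b] == "", TRUE))) {
        g$marks[c, a] <- "t"
        changed <- TRUE
      }
    }
    ## R10: a o-> c; b -> c and d -> c; uncovered p.d. paths a..b and a..d
    ##      whose first vertices mu != omega are nonadjacent => a -> c
    for (a in seq_len(N)) for (c in seq_len(N)) {
      if (a == c || !(g$marks[c, a] == "c" && g$marks[a, c] == "a")) next
      parents <- which(vapply(seq_len(N), function(v)
        v != c && g$marks[v, c] == "a" && g$marks[c, v] == "t", TRUE))
      parents <- setdiff(parents, a)
      if (length(parents) < 2L) next
      done <- FALSE
      for (bi in seq_along(parents)) {
        if (done) break
        for (di in seq_along(parents)) {
          if (bi >= di) next
          bb <- parents[bi]; dd <- parents[di]
          mus <- ucp_first_vertices(g, a, bb)
          oms <- ucp_first_vertices(g, a, dd)
          ok <- FALSE
          for (mu in mus) for (om in oms) {
            if (mu != om && g$marks[mu, om] == "" && g$marks[om, mu] == "")
              ok <- TRUE
          }
          if (ok) { g$marks[c, a] <- "t"; changed <- TRUE; done <- TRUE; break }
        }
      }
    }
    if (!changed) break
  }
  g
}

#' FCI causal discovery with PAG output
#'
#' PC-Stable skeleton, majority-rule collider orientation, possible-D-SEP
#' pruning, re-orientation, and Zhang's orientation rules to fixpoint.
#' Output endpoint marks are tails, arrows, and circles, encoding the
#' partial ancestral graph semantics: `X <-> Y` indicates a shared latent
#' confounder; `X o-> Y` indicates that Y is not a cause of X.
#'
#' @inheritParams pc_stable_skeleton
#' @return An `endpoint_graph` tagged `"pag"`.
#' @export
fci <- function(init, tester, alpha = 0.05, max_depth = 3L) {
  sk <- pc_stable_skeleton(init, tester, alpha, max_depth)
  g0 <- orient_colliders_majority(sk$graph, tester, alpha, max_depth,
                                  circles = TRUE)
  ## possible-D-SEP pruning
  g1 <- g0
  e <- graph_edges(g1)
  if (nrow(e)) for (k in seq_len(nrow(e))) {
    x <- e$a[k]; y <- e$b[k]
    if (!has_edge(g1, x, y)) next
    removed <- FALSE
    for (anchor in c(x, y)) {
      if (removed) break
      pd <- setdiff(possible_dsep(g0, anchor), c(x, y))
      for (d in seq_len(min(length(pd), max_depth))) {
        if (removed) break
        for (S in subsets_of(pd, d)) {
          p <- tryCatch(tester(x, y, S), error = function(err) NA_real_)
          if (!is.na(p) && p > alpha) {
            g1 <- remove_edge(g1, x, y)
            key <- paste(sort(c(x, y)), collapse = "|")
            sk$sepsets[[key]] <- c(sk$sepsets[[key]], list(list(S = S, p = p)))
            removed <- TRUE
            break
          }
        }
      }
    }
  }
  ## re-orient on the pruned skeleton
  skel2 <- g1
  skel2$marks[skel2$marks != ""] <- "t"
  skel2$gclass <- "skeleton"
  g2 <- orient_colliders_majority(skel2, tester, alpha, max_depth,
                                  circles = TRUE)
  sep_lookup <- function(dn, cn, bn) {
    seps <- collect_sepsets(skel2, dn, cn, tester, alpha, max_depth)
    if (!length(seps)) return(NA)
    mean(vapply(seps, function(S) bn %in% S, TRUE)) >= 0.5
  }
  g2 <- zhang_closure(g2, sep_lookup)
  g2$gclass <- "pag"
  g2
}

#' Markov blanket of a node in a DAG, CPDAG, or PAG
#'
#' DAG/CPDAG: parents, children, and co-parents of children, counting
#' undirected neighbours as possible parents/children. PAG: adjacent nodes
#' plus nodes with an arrowhead into a common child.
#'
#' @param g An `endpoint_graph` tagged `"dag"`, `"cpdag"`, or `"pag"`.
#' @param node Node name.
#' @return Character vector of blanket members (node excluded).
#' @export
markov_blanket <- function(g, node) {
  i <- node_index(g, node)
  nodes <- g$nodes
  N <- length(nodes)
  mb <- adj_of(g, i)
  if (g$gclass %in% c("dag", "cpdag", "skeleton")) {
    ## possible children: edge i ~ c not pointing into i
    ch <- Filter(function(c) g$marks[c, i] != "a", mb)
    for (c in ch) {
      copar <- Filter(function(w) w != i && g$marks[c, w] != "a",
                      adj_of(g, c))
      mb <- union(mb, copar)
    }
  } else {
    ## PAG: arrowhead into a common "child" (arrowhead from both sides)
    for (c in mb) {
      if (g$marks[i, c] != "a") next
      others <- Filter(function(w) w != i && g$marks[w, c] == "a", adj_of(g, c))
      mb <- union(mb, others)
    }
  }
  setdiff(nodes[sort(unique(mb))], nodes[i])
}

#' Configuration for the full CausalCoxMGM pipeline
#'
#' @param alpha CI-test significance level.
#' @param max_depth Maximum conditioning-set size (default 3).
#' @param mode `"mpc"` (CPDAG output) or `"fci"` (PAG output).
#' @param selection `"steps"`, `"stars"`, or `"bic"`.
#' @param K Penalty-path length. @param B Subsample count.
#' @param stability_threshold StEPS/StARS instability threshold.
#' @param fit_tol,fit_max_iter CoxMGM optimizer controls.
#' @param seed Master seed (drives subsampling).
#' @return A list of class `"causal_config"`.
#' @export
causal_config <- function(alpha = 0.05, max_depth = 3L,
                          mode = c("mpc", "fci"),
                          selection = c("steps", "stars", "bic"),
                          K = 30L, B = 20L, stability_threshold = 0.05,
                          fit_tol = 1e-5, fit_max_iter = 500L, seed = 1L) {
  structure(list(alpha = alpha, max_depth = as.integer(max_depth),
                 mode = match.arg(mode), selection = match.arg(selection),
                 K = as.integer(K), B = as.integer(B),
                 stability_threshold = stability_threshold,
                 fit_tol = fit_tol, fit_max_iter = as.integer(fit_max_iter),
                 seed = as.integer(seed)),
            class = "causal_config")
}

#' CausalCoxMGM: the full two-step pipeline
#'
#' Step 1 learns an undirected CoxMGM skeleton at penalties selected by
#' StEPS (default), StARS, or BIC. Step 2 prunes and orients the skeleton
#' with MPC-Stable (default) or FCI using the censoring-aware CI test.
#' Deterministic given `config$seed`.
#'
#' @param data A `mixed_dataset`.
#' @param config A [causal_config()].
#' @return List with `graph` (CPDAG or PAG), `skeleton`, `fit`, `lambda`,
#'   `profile` (NULL for BIC), `config`.
#' @export
causal_cox_mgm <- function(data, config = causal_config()) {
  path <- build_lambda_path(data, config$K, tol = config$fit_tol)
  profile <- NULL
  if (config$selection == "bic") {
    sel <- bic_select(data, path, tol = config$fit_tol,
                      max_iter = config$fit_max_iter)
    lambda <- sel$lambda
  } else {
    profile <- stability_profile(data, path, B = config$B, seed = config$seed,
                                 tol = config$fit_tol,
                                 max_iter = config$fit_max_iter)
    lambda <- if (config$selection == "steps")
      steps_select(profile, config$stability_threshold)
    else stars_select(profile, config$stability_threshold)
  }
  fit <- fit_coxmgm(data, lambda, tol = config$fit_tol,
                    max_iter = config$fit_max_iter)
  skeleton <- params_to_graph(fit)
  tester <- ci_tester(data, ci_config(alpha = config$alpha,
                                      max_cond_size = config$max_depth))
  graph <- if (config$mode == "mpc") {
    mpc_stable(skeleton, tester, config$alpha, config$max_depth)
  } else {
    fci(skeleton, tester, config$alpha, config$max_depth)
  }
  list(graph = graph, skeleton = skeleton, fit = fit, lambda = lambda,
       profile = profile, config = config)
}
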
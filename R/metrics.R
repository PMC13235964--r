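## Graph-recovery evaluation: adjacency and orientation confusion per edge
## class, precision/recall/F1, AUPRC over hyperparameter sweeps, and
## structural Hamming distance from the Markov equivalence class (MEC).

#' Convert a DAG to its CPDAG (Markov equivalence class representative)
#'
#' Orients the v-structures of the DAG's skeleton and applies Meek closure;
#' an edge stays directed iff it is compelled. Two Markov-equivalent DAGs
#' (same skeleton and v-structures) map to the identical CPDAG.
#'
#' @param dag An `endpoint_graph` tagged `"dag"` (acyclic).
#' @return An `endpoint_graph` tagged `"cpdag"`.
#' @export
dag_to_cpdag <- function(dag) {
  A <- dag_amat(dag)
  topological_order(A)                     # errors on cyclic input
  N <- nrow(A)
  g <- dag
  g$gclass <- "cpdag"
  g$marks[g$marks != ""] <- "t"            # undirected skeleton
  ## orient v-structures a -> z <- b with a, b nonadjacent
  for (z in seq_len(N)) {
    pa <- which(A[, z] == 1L)
    if (length(pa) < 2L) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i >= j) next
      a <- pa[i]; b <- pa[j]
      if (A[a, b] == 0L && A[b, a] == 0L) {
        g$marks[a, z] <- "a"; g$marks[z, a] <- "t"
        g$marks[b, z] <- "a"; g$marks[z, b] <- "t"
      }
    }
  }
  ## Meek closure orients the remaining compelled edges; restrict rules so
  ## they only ever direct edges consistently with the DAG (Meek rules are
  ## sound, so closure equals the compelled set)
  meek_closure(g)
}

## per-pair class labels for a graph with kinds; "ALL" when kinds missing
pair_class_matrix <- function(g) {
  N <- length(g$nodes)
  if (is.null(g$kinds)) return(matrix("ALL", N, N))
  k1 <- substr(g$kinds, 1, 1)
  k1[g$kinds == "censored"] <- "s"
  out <- matrix("", N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    key <- paste(sort(c(k1[i], k1[j])), collapse = "")
    out[i, j] <- switch(key, cc = "CC", cd = "CD", dd = "DD",
                        cs = "SC", ds = "SD", ss = "SS", "ALL")
  }
  out
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else
      if (isTRUE(tp + fp + fn == 0)) NA_real_ else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Adjacency confusion counts against a true DAG
#'
#' Over unordered node pairs (restricted to `edge_class` by endpoint kinds):
#' TP = adjacent in both, FP = adjacent in the estimate only, FN = in the
#' truth only, TN = in neither.
#'
#' @param est Estimated `endpoint_graph`.
#' @param truth_dag True DAG (`endpoint_graph`).
#' @param edge_class One of "ALL", "CC", "CD", "DD", "SC", "SD".
#' @return List with counts and precision/recall/F1.
#' @export
adjacency_confusion <- function(est, truth_dag, edge_class = "ALL") {
  if (!identical(sort(est$nodes), sort(truth_dag$nodes)))
    stop("node-set mismatch")
  ord <- match(est$nodes, truth_dag$nodes)
  Aest <- est$marks != ""
  Atru <- (truth_dag$marks != "")[ord, ord]
  cls <- pair_class_matrix(est)
  up <- upper.tri(Aest)
  keep <- up & (edge_class == "ALL" | cls == edge_class)
  tp <- sum(Aest[keep] & Atru[keep])
  fp <- sum(Aest[keep] & !Atru[keep])
  fn <- sum(!Aest[keep] & Atru[keep])
  tn <- sum(!Aest[keep] & !Atru[keep])
  c(list(tp = tp, fp = fp, fn = fn, tn = tn), prf(tp, fp, fn))
}

#' Orientation confusion counts against the MEC of a true DAG
#'
#' Evaluated over pairs adjacent in both the estimate and the CPDAG of the
#' truth: TP = endpoint marks match the MEC's; FP = the estimate asserts an
#' orientation contradicting the MEC's marks; FN = the MEC directs the edge
#' but the estimate leaves it unoriented (circle marks count as unoriented)
#' or mis-oriented.
#'
#' @inheritParams adjacency_confusion
#' @return List with counts and precision/recall/F1.
#' @export
orientation_confusion <- function(est, truth_dag, edge_class = "ALL") {
  if (!identical(sort(est$nodes), sort(truth_dag$nodes)))
    stop("node-set mismatch")
  mec <- if (truth_dag$gclass == "cpdag") truth_dag else dag_to_cpdag(truth_dag)
  ord <- match(est$nodes, mec$nodes)
  Mtru <- mec$marks[ord, ord]
  Mest <- est$marks
  cls <- pair_class_matrix(est)
  N <- length(est$nodes)
  tp <- fp <- fn <- 0L
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    if (edge_class != "ALL" && cls[i, j] != edge_class) next
    if (Mest[i, j] == "" || Mtru[i, j] == "") next   # not shared adjacency
    est_pair <- c(Mest[j, i], Mest[i, j])            # marks at i, at j
    tru_pair <- c(Mtru[j, i], Mtru[i, j])
    if (identical(est_pair, tru_pair)) {
      tp <- tp + 1L
    } else {
      est_oriented <- any(est_pair == "a")
      tru_directed <- any(tru_pair == "a")
      if (est_oriented) fp <- fp + 1L
      if (tru_directed) fn <- fn + 1L
    }
  }
  c(list(tp = tp, fp = fp, fn = fn), prf(tp, fp, fn))
}

#' Area under a precision-recall curve
#'
#' Sorts points by recall, prepends `(0, precision of the first point)`,
#' and integrates by trapezoid. When the maximum achieved recall is below
#' 1 the curve is not extrapolated (conservative: the area over the
#' unachieved recall range counts as 0, and the result is still divided
#' by 1).
#'
#' @param points A data.frame or matrix with columns `recall`, `precision`
#'   (or a list of `(recall, precision)` pairs).
#' @return AUPRC in `[0, 1]`.
#' @export
pr_curve_auprc <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(recall = p[[1]], precision = p[[2]])))
  points <- as.data.frame(points)
  if (!nrow(points)) stop("empty point list")
  stopifnot(all(points$recall >= 0 & points$recall <= 1),
            all(points$precision >= 0 & points$precision <= 1))
  points <- points[order(points$recall), , drop = FALSE]
  r <- c(0, points$recall)
  p <- c(points$precision[1L], points$precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Structural Hamming distance from the MEC of the true DAG
#'
#' Against `dag_to_cpdag(truth)`: +1 per missing adjacency, +1 per extra
#' adjacency, +1 per shared adjacency whose endpoint marks differ.
#' `normalized` divides by the MEC's edge count.
#'
#' @inheritParams adjacency_confusion
#' @return List with `shd` (integer) and `normalized`.
#' @export
shd <- function(est, truth_dag) {
  if (!identical(sort(est$nodes), sort(truth_dag$nodes)))
    stop("node-set mismatch")
  mec <- if (truth_dag$gclass == "cpdag") truth_dag else dag_to_cpdag(truth_dag)
  ord <- match(est$nodes, mec$nodes)
  Mtru <- mec$marks[ord, ord]
  Mest <- est$marks
  N <- length(est$nodes)
  d <- 0L
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    e <- Mest[i, j] != ""; t <- Mtru[i, j] != ""
    if (e != t) d <- d + 1L
    else if (e && t &&
             !(Mest[i, j] == Mtru[i, j] && Mest[j, i] == Mtru[j, i]))
      d <- d + 1L
  }
  me <- sum(Mtru != "") / 2
  list(shd = d, normalized = if (me > 0) d / me else NA_real_)
}

#' Full graph-recovery report
#'
#' Assembles adjacency and orientation confusion (per edge class), SHD,
#' and optional PR points into one report.
#'
#' @inheritParams adjacency_confusion
#' @param pr_points Optional PR-curve points (see [pr_curve_auprc()]).
#' @return An object of class `"metrics_report"` (a nested list).
#' @export
evaluate_run <- function(est, truth_dag, pr_points = NULL) {
  classes <- c("ALL", "CC", "CD", "DD", "SC", "SD")
  adjacency <- lapply(classes, function(cl) adjacency_confusion(est, truth_dag, cl))
  orientation <- lapply(classes, function(cl) orientation_confusion(est, truth_dag, cl))
  names(adjacency) <- names(orientation) <- classes
  out <- list(adjacency = adjacency, orientation = orientation,
              shd = shd(est, truth_dag))
  if (!is.null(pr_points)) {
    out$pr_points <- as.data.frame(pr_points)
    out$auprc <- pr_curve_auprc(pr_points)
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$adjacency$ALL; o <- x$orientation$ALL
  cat(sprintf("adjacency  P=%.3f R=%.3f F1=%.3f (TP=%d FP=%d FN=%d)\n",
              a$precision, a$recall, a$f1, a$tp, a$fp, a$fn))
  cat(sprintf("orientation P=%.3f R=%.3f F1=%.3f\n",
              o$precision, o$recall, o$f1))
  cat(sprintf("SHD = %d (normalized %.3f)\n", x$shd$shd, x$shd$normalized))
  if (!is.null(x$auprc)) cat(sprintf("AUPRC = %.3f\n", x$auprc))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
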
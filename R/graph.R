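## Endpoint-marked graphs.
##
## One structure represents undirected skeletons, CPDAGs, DAGs, and PAGs.
## marks[i, j] is the endpoint mark AT node j of the edge i ~ j:
##   "t" tail, "a" arrow, "c" circle, "" no edge.
## An edge i -> j is marks[j, i] = "t", marks[i, j] = "a".

#' Create an endpoint-marked graph
#'
#' @param nodes Character vector of node names.
#' @param kinds Optional named kinds (`"continuous"`, `"discrete"`,
#'   `"censored"`) per node.
#' @param gclass Graph class tag: `"skeleton"`, `"cpdag"`, `"pag"`, `"dag"`.
#' @return An object of class `"endpoint_graph"`.
#' @export
endpoint_graph <- function(nodes, kinds = NULL,
                           gclass = c("skeleton", "cpdag", "pag", "dag")) {
  gclass <- match.arg(gclass)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  N <- length(nodes)
  marks <- matrix("", N, N, dimnames = list(nodes, nodes))
  if (!is.null(kinds)) {
    kinds <- kinds[nodes]
    names(kinds) <- nodes
  }
  structure(list(nodes = nodes, kinds = kinds, marks = marks, gclass = gclass),
            class = "endpoint_graph")
}

node_index <- function(g, v) {
  if (is.character(v)) {
    i <- match(v, g$nodes)
    if (anyNA(i)) stop("unknown node: ", paste(v[is.na(i)], collapse = ", "))
    i
  } else as.integer(v)
}

#' Add an edge with endpoint marks
#' @param g An `endpoint_graph`.
#' @param i,j Node names or indices.
#' @param mi,mj Marks at the `i` and `j` ends (`"t"`, `"a"`, `"c"`).
#' @return Updated graph.
#' @export
add_edge <- function(g, i, j, mi = "t", mj = "t") {
  i <- node_index(g, i); j <- node_index(g, j)
  if (i == j) stop("self-loop")
  stopifnot(mi %in% c("t", "a", "c"), mj %in% c("t", "a", "c"))
  g$marks[i, j] <- mj
  g$marks[j, i] <- mi
  g
}

#' @rdname add_edge
#' @export
remove_edge <- function(g, i, j) {
  i <- node_index(g, i); j <- node_index(g, j)
  g$marks[i, j] <- ""
  g$marks[j, i] <- ""
  g
}

#' @rdname add_edge
#' @export
has_edge <- function(g, i, j) {
  i <- node_index(g, i); j <- node_index(g, j)
  g$marks[i, j] != ""
}

## adjacency indices of node i
adj_of <- function(g, i) which(g$marks[node_index(g, i), ] != "")

## number of edges
n_edges <- function(g) sum(g$marks != "") / 2

#' Edge list of an endpoint graph
#' @param g An `endpoint_graph`.
#' @return data.frame with columns `a`, `b` (names, a before b in node order),
#'   `ma`, `mb` (marks at the a and b ends).
#' @export
graph_edges <- function(g) {
  idx <- which(g$marks != "" & upper.tri(g$marks), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      ma = character(0), mb = character(0)))
  data.frame(a = g$nodes[idx[, 1L]], b = g$nodes[idx[, 2L]],
             ma = g$marks[idx[, 2L] + (idx[, 1L] - 1L) * nrow(g$marks)],
             mb = g$marks[idx[, 1L] + (idx[, 2L] - 1L) * nrow(g$marks)],
             stringsAsFactors = FALSE)
}

#' @export
print.endpoint_graph <- function(x, ...) {
  cat("endpoint_graph [", x$gclass, "]: ", length(x$nodes), " nodes, ",
      n_edges(x), " edges\n", sep = "")
  e <- graph_edges(x)
  if (nrow(e)) {
    tok <- mapply(marks_to_token, e$ma, e$mb)
    cat(paste0("  ", e$a, " ", tok, " ", e$b, collapse = "\n"), "\n")
  }
  invisible(x)
}

## --- edge token vocabulary -------------------------------------------------

marks_to_token <- function(ma, mb) {
  key <- paste0(ma, mb)
  switch(key,
         "tt" = "---", "ta" = "-->", "at" = "<--",
         "aa" = "<->", "ca" = "o->", "ac" = "<-o",
         "cc" = "o-o",
         stop("no token for mark pair ", key))
}

token_to_marks <- function(tok) {
  switch(tok,
         "---" = c("t", "t"), "-->" = c("t", "a"), "<--" = c("a", "t"),
         "<->" = c("a", "a"), "o->" = c("c", "a"), "<-o" = c("a", "c"),
         "o-o" = c("c", "c"),
         NULL)
}

#' Write an endpoint graph to its text format
#'
#' Format: a header line `#nodes:` followed by tab-separated node names, then
#' one line per edge `NAME1 <tok> NAME2` with tokens `---`, `-->`, `<->`,
#' `o->`, `o-o` (the reversed forms `<--`, `<-o` are accepted on input only).
#' Output is canonical: edges with a symmetric token (`---`, `<->`, `o-o`)
#' put the lexicographically smaller node first; directed or partially
#' directed edges are written in forward form (non-arrow end first). Edges
#' are sorted by the emitted node pair.
#'
#' @param g An `endpoint_graph`.
#' @param path Output path.
#' @export
write_graph_file <- function(g, path) {
  lines <- paste0("#nodes:\t", paste(g$nodes, collapse = "\t"))
  e <- graph_edges(g)
  if (nrow(e)) {
    sym <- e$ma == e$mb
    swap <- (sym & e$a > e$b) | (!sym & e$ma == "a")
    tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
    tmpm <- e$ma[swap]; e$ma[swap] <- e$mb[swap]; e$mb[swap] <- tmpm
    e <- e[order(e$a, e$b), , drop = FALSE]
    tok <- mapply(marks_to_token, e$ma, e$mb)
    lines <- c(lines, paste(e$a, tok, e$b))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an endpoint graph from its text format
#' @param path Input path.
#' @param gclass Graph class tag for the result.
#' @return An `endpoint_graph`.
#' @export
read_graph_file <- function(path, gclass = "skeleton") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], "#nodes:"))
    stop("malformed graph file: missing '#nodes:' header")
  nodes <- strsplit(sub("^#nodes:\t?", "", lines[1L]), "\t")[[1L]]
  g <- endpoint_graph(nodes, gclass = gclass)
  for (ln in seq_along(lines)[-1L]) {
    parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(parts) != 3L)
      stop("malformed line ", ln, ": '", lines[ln], "'")
    mk <- token_to_marks(parts[2L])
    if (is.null(mk))
      stop("unknown mark token '", parts[2L], "' at line ", ln)
    if (has_edge(g, parts[1L], parts[3L]))
      stop("duplicate edge at line ", ln)
    g <- add_edge(g, parts[1L], parts[3L], mk[1L], mk[2L])
  }
  g
}

## --- DAG utilities ---------------------------------------------------------

## adjacency matrix (i->j) of a DAG-tagged endpoint graph
dag_amat <- function(g) {
  N <- length(g$nodes)
  A <- matrix(0L, N, N, dimnames = list(g$nodes, g$nodes))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j && g$marks[i, j] == "a" && g$marks[j, i] == "t") A[i, j] <- 1L
  }
  A
}

amat_to_dag <- function(A, kinds = NULL) {
  g <- endpoint_graph(rownames(A) %||% paste0("V", seq_len(nrow(A))),
                      kinds = kinds, gclass = "dag")
  idx <- which(A == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) g <- add_edge(g, idx[k, 1L], idx[k, 2L], "t", "a")
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' d-separation in a DAG
#'
#' Tests whether `x` and `y` are d-separated given `S` by the ancestral
#' moralization criterion: restrict to ancestors of `{x, y} union S`,
#' moralize, delete `S`, and check connectivity.
#'
#' @param amat DAG adjacency matrix (`amat[i,j] = 1` means i -> j).
#' @param x,y Node indices.
#' @param S Integer vector of conditioning node indices (possibly empty).
#' @return `TRUE` if d-separated.
#' @export
dsep <- function(amat, x, y, S = integer(0)) {
  N <- nrow(amat)
  keep <- rep(FALSE, N)
  frontier <- unique(c(x, y, S))
  keep[frontier] <- TRUE
  while (length(frontier)) {
    pa <- which(rowSums(amat[, frontier, drop = FALSE]) > 0)
    new <- pa[!keep[pa]]
    keep[new] <- TRUE
    frontier <- new
  }
  sub <- which(keep)
  A <- amat[sub, sub, drop = FALSE]
  ## moralize: undirected adjacency + marry parents of common children
  U <- (A + t(A)) > 0
  for (j in seq_len(ncol(A))) {
    pa <- which(A[, j] == 1L)
    if (length(pa) > 1L) U[pa, pa] <- TRUE
  }
  diag(U) <- FALSE
  ## delete S, test reachability x -> y
  Sloc <- match(intersect(S, sub), sub)
  xi <- match(x, sub); yi <- match(y, sub)
  alive <- setdiff(seq_along(sub), Sloc)
  if (!(xi %in% alive) || !(yi %in% alive)) return(TRUE)
  reach <- rep(FALSE, length(sub))
  reach[xi] <- TRUE
  frontier <- xi
  while (length(frontier)) {
    nb <- which(rowSums(U[, frontier, drop = FALSE]) > 0)
    nb <- intersect(nb, alive)
    new <- nb[!reach[nb]]
    reach[new] <- TRUE
    frontier <- new
  }
  !reach[yi]
}

#' Meek orientation rules to fixpoint
#'
#' Applies Meek rules R1-R4 to a partially directed graph (tail/arrow marks)
#' until no rule fires. Idempotent; introduces no new unshielded colliders.
#'
#' @param g An `endpoint_graph` with tail/arrow marks.
#' @return Closed graph.
#' @export
meek_closure <- function(g) {
  N <- length(g$nodes)
  directed <- function(a, b) g$marks[b, a] == "t" && g$marks[a, b] == "a"
  undirected <- function(a, b) g$marks[a, b] == "t" && g$marks[b, a] == "t"
  adjacent <- function(a, b) g$marks[a, b] != ""
  repeat {
    changed <- FALSE
    for (b in seq_len(N)) for (c in seq_len(N)) {
      if (b == c || !undirected(b, c)) next
      orient <- FALSE
      ## R1: a -> b - c, a and c nonadjacent  =>  b -> c
      for (a in seq_len(N)) {
        if (a != c && directed(a, b) && !adjacent(a, c)) { orient <- TRUE; break }
      }
      ## R2: b -> a -> c with b - c  =>  b -> c
      if (!orient) for (a in seq_len(N)) {
        if (a != b && a != c && directed(b, a) && directed(a, c)) { orient <- TRUE; break }
      }
      ## R3: b - a1 -> c, b - a2 -> c, a1 a2 nonadjacent  =>  b -> c
      if (!orient) {
        cand <- which(vapply(seq_len(N), function(a)
          a != b && a != c && undirected(b, a) && directed(a, c), TRUE))
        if (length(cand) >= 2L) {
          for (ii in seq_along(cand)) for (jj in seq_along(cand)) {
            if (ii < jj && !adjacent(cand[ii], cand[jj])) { orient <- TRUE; break }
          }
        }
      }
      ## R4: b - x, x -> y, y -> c, x and c nonadjacent, b adjacent y
      ##     => b -> c
      if (!orient) {
        for (x in seq_len(N)) {
          if (x %in% c(b, c) || !undirected(b, x)) next
          for (y in seq_len(N)) {
            if (y %in% c(b, c, x)) next
            if (directed(x, y) && directed(y, c) &&
                !adjacent(x, c) && adjacent(b, y)) { orient <- TRUE; break }
          }
          if (orient) break
        }
      }
      if (orient) {
        g$marks[b, c] <- "a"; g$marks[c, b] <- "t"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}
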
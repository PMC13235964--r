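#' Declare a variable for a mixed dataset
#'
#' A `variable_spec` declares one modeled variable: continuous, discrete
#' (with an ordered level set), or censored (a time-to-event variable backed
#' by a time column and a binary event-indicator column).
#'
#' @param name Variable name.
#' @param kind One of `"continuous"`, `"discrete"`, `"censored"`.
#' @param levels For discrete variables, the ordered level set (optional;
#'   inferred from data when omitted).
#' @param time_col,event_col For censored variables, the names of the two
#'   distinct source columns holding observation time and event indicator.
#' @return An object of class `"variable_spec"`.
#' @export
variable_spec <- function(name, kind = c("continuous", "discrete", "censored"),
                          levels = NULL, time_col = NULL, event_col = NULL) {
  kind <- match.arg(kind)
  if (kind == "censored") {
    if (is.null(time_col) || is.null(event_col))
      stop("censored variable '", name, "' needs time_col and event_col")
    if (identical(time_col, event_col))
      stop("censored variable '", name, "' must reference two distinct columns")
  }
  structure(list(name = name, kind = kind, levels = levels,
                 time_col = time_col, event_col = event_col),
            class = "variable_spec")
}

#' Read variable specs from a YAML/JSON sidecar
#'
#' The sidecar is a list of entries `{name, kind, levels?, time_col?,
#' event_col?}` declaring every modeled variable of a delimited data file.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` sidecar.
#' @return List of [variable_spec()] objects.
#' @export
read_variable_specs <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else yaml::read_yaml(path)
  lapply(raw, function(e) {
    variable_spec(e$name, e$kind,
                  levels = if (!is.null(e$levels)) as.character(e$levels),
                  time_col = e$time_col, event_col = e$event_col)
  })
}

#' Write variable specs to a YAML sidecar
#' @param specs List of [variable_spec()] objects.
#' @param path Output path.
#' @export
write_variable_specs <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(s) {
    out <- list(name = s$name, kind = s$kind)
    if (!is.null(s$levels)) out$levels <- s$levels
    if (!is.null(s$time_col)) out$time_col <- s$time_col
    if (!is.null(s$event_col)) out$event_col <- s$event_col
    out
  }), path)
}

#' Validate a raw table against variable specs and build a mixed dataset
#'
#' Performs complete-case filtering (rows with any missing value in a modeled
#' column are dropped and counted), checks all invariants (nonnegative times,
#' binary event indicators, discrete values within declared levels), and
#' returns a `mixed_dataset` holding an n x p continuous matrix, an n x q
#' table of factors, and r censored (time, event) pairs.
#'
#' @param raw_table A data.frame with named columns.
#' @param specs List of [variable_spec()] objects.
#' @return An object of class `"mixed_dataset"` with fields `sample_ids`,
#'   `continuous`, `discrete`, `time`, `event`, `specs`, `n`, `p`, `q`, `r`,
#'   `dropped` (count of incomplete rows removed).
#' @export
validate_dataset <- function(raw_table, specs) {
  raw_table <- as.data.frame(raw_table)
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  used_cols <- unlist(lapply(specs, function(s) {
    if (s$kind == "censored") c(s$time_col, s$event_col) else s$name
  }))
  missing_cols <- setdiff(used_cols, names(raw_table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))

  sub <- raw_table[, used_cols, drop = FALSE]
  sub[sub == "NA"] <- NA
  complete <- stats::complete.cases(sub)
  dropped <- sum(!complete)
  if (dropped > 0)
    message("validate_dataset: dropped ", dropped, " incomplete row(s)")
  sub <- sub[complete, , drop = FALSE]
  if (nrow(sub) == 0L) stop("zero rows after filtering")
  n <- nrow(sub)

  kinds <- vapply(specs, `[[`, "", "kind")
  names(kinds) <- vapply(specs, `[[`, "", "name")
  cont_specs <- specs[kinds == "continuous"]
  disc_specs <- specs[kinds == "discrete"]
  cens_specs <- specs[kinds == "censored"]

  continuous <- matrix(0, n, length(cont_specs),
                       dimnames = list(NULL, vapply(cont_specs, `[[`, "", "name")))
  for (s in cont_specs) {
    v <- suppressWarnings(as.numeric(sub[[s$name]]))
    if (anyNA(v)) stop("non-numeric value in continuous column '", s$name, "'")
    continuous[, s$name] <- v
  }

  discrete <- as.data.frame(matrix(nrow = n, ncol = 0))
  for (s in disc_specs) {
    v <- as.character(sub[[s$name]])
    lev <- if (is.null(s$levels)) sort(unique(v)) else s$levels
    bad <- setdiff(unique(v), lev)
    if (length(bad))
      stop("discrete value(s) outside declared levels in '", s$name, "': ",
           paste(bad, collapse = ", "))
    discrete[[s$name]] <- factor(v, levels = lev)
  }

  tm <- matrix(0, n, length(cens_specs),
               dimnames = list(NULL, vapply(cens_specs, `[[`, "", "name")))
  ev <- tm
  for (s in cens_specs) {
    tv <- suppressWarnings(as.numeric(sub[[s$time_col]]))
    dv <- suppressWarnings(as.numeric(sub[[s$event_col]]))
    if (anyNA(tv) || anyNA(dv))
      stop("non-numeric time/event values for censored variable '", s$name, "'")
    if (any(tv < 0)) stop("negative time in '", s$name, "'")
    if (!all(dv %in% c(0, 1))) stop("non-binary event indicator in '", s$name, "'")
    tm[, s$name] <- tv
    ev[, s$name] <- dv
  }

  ids <- rownames(raw_table)[complete]
  if (is.null(ids)) ids <- as.character(which(complete))
  structure(list(sample_ids = ids,
                 continuous = continuous,
                 discrete = discrete,
                 time = tm, event = ev,
                 specs = specs,
                 n = n, p = ncol(continuous), q = ncol(discrete), r = ncol(tm),
                 dropped = dropped),
            class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  cat("mixed_dataset: n =", x$n, "| continuous:", x$p,
      "discrete:", x$q, "censored:", x$r, "\n")
  invisible(x)
}

## All modeled variable names, in continuous / discrete / censored block order.
dataset_var_names <- function(data) {
  c(colnames(data$continuous), names(data$discrete), colnames(data$time))
}

## Kind ("continuous"/"discrete"/"censored") of each variable, named vector.
dataset_var_kinds <- function(data) {
  k <- c(rep("continuous", data$p), rep("discrete", data$q),
         rep("censored", data$r))
  names(k) <- dataset_var_names(data)
  k
}

## Subset rows of a mixed dataset (used by subsampling and cross-validation).
dataset_subset <- function(data, idx) {
  out <- data
  out$sample_ids <- data$sample_ids[idx]
  out$continuous <- data$continuous[idx, , drop = FALSE]
  out$discrete <- data$discrete[idx, , drop = FALSE]
  out$discrete <- as.data.frame(lapply(out$discrete, droplevels_keep))
  out$time <- data$time[idx, , drop = FALSE]
  out$event <- data$event[idx, , drop = FALSE]
  out$n <- length(idx)
  out
}

## keep declared levels (do NOT droplevels: encoding widths must be stable)
droplevels_keep <- function(f) f

#' Nonparanormal (Gaussian copula) marginal transform
#'
#' Maps a continuous column to Winsorized empirical ranks pushed through the
#' standard normal quantile function. The truncation level is
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`; tied values share average
#' ranks. The result is invariant under strictly increasing transforms of the
#' input.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Transformed numeric vector.
#' @export
nonparanormal_transform <- function(x) {
  n <- length(x)
  if (length(unique(x)) < 2L) stop("constant column")
  delta <- 1 / (4 * n^(1/4) * sqrt(pi * log(n)))
  u <- rank(x, ties.method = "average") / n
  u <- pmin(pmax(u, delta), 1 - delta)
  stats::qnorm(u)
}

#' Indicator encoding of a discrete column
#'
#' Full encoding (one indicator per level) supports the group penalties of
#' the graphical model; reference encoding (dropping the first declared
#' level) is used wherever a regression requires identifiability.
#'
#' @param y A factor (declared levels define column order).
#' @param reference If `TRUE`, drop the first level's indicator.
#' @return Numeric indicator matrix with one row per observation.
#' @export
encode_discrete <- function(y, reference = FALSE) {
  y <- as.factor(y)
  lev <- levels(y)
  if (length(unique(as.integer(y))) < 2L)
    stop("single observed level")
  M <- matrix(0, length(y), length(lev), dimnames = list(NULL, lev))
  M[cbind(seq_along(y), as.integer(y))] <- 1
  if (reference) M <- M[, -1L, drop = FALSE]
  M
}

## Unchecked indicator encoding for internal model code (tolerates subsamples
## where a level happens not to occur; declared levels fix the width).
indicator_matrix <- function(y, reference = FALSE) {
  y <- as.factor(y)
  lev <- levels(y)
  M <- matrix(0, length(y), length(lev), dimnames = list(NULL, lev))
  M[cbind(seq_along(y), as.integer(y))] <- 1
  if (reference) M <- M[, -1L, drop = FALSE]
  M
}

## Standardize continuous block (zero mean, unit variance); returns dataset.
standardize_continuous <- function(data) {
  if (data$p > 0) {
    ctr <- scale(data$continuous)
    ctr[is.nan(ctr)] <- 0
    data$continuous <- matrix(as.numeric(ctr), nrow(ctr), ncol(ctr),
                              dimnames = dimnames(data$continuous))
  }
  data
}
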
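#' Define a recursive path-model specification
#'
#' A path model over observed variables: a set of directed causal edges
#' (`target ~ source`), optional undirected correlation edges (`a ~~ b`,
#' free covariances between disturbances or exogenous variables), and an
#' optional grouping of variables into blocks (biomass, taxonomic profile,
#' functional profile, physiological potential, respiration, soil
#' chemistry, tree diversity, ...). The directed subgraph must be acyclic;
#' variables with no incoming directed edge are exogenous, and their
#' covariance block is free (saturated) in the fit.
#'
#' @param edges data.frame with columns `source`, `target` (one row per
#'   directed edge).
#' @param correlations optional data.frame with columns `a`, `b`.
#' @param groups optional named list: group name -> character vector of
#'   variables; every model variable must belong to exactly one group if
#'   groups are given.
#' @param variables optional explicit variable ordering; defaults to the
#'   variables appearing in the edges.
#' @return object of class `path_spec`.
#' @seealso [read_path_spec()] for the plain-text format,
#'   [fit_path_model()] to fit.
#' @export
path_spec <- function(edges, correlations = NULL, groups = NULL,
                      variables = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target") %in% names(edges)))
  vars <- unique(c(variables, edges$source, edges$target,
                   if (!is.null(correlations)) unlist(correlations[c("a", "b")])))
  order <- topo_order(vars, edges)  # errors on cycles
  exogenous <- setdiff(vars, unique(edges$target))
  if (!is.null(correlations)) {
    correlations <- as.data.frame(correlations, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b") %in% names(correlations)))
  }
  if (!is.null(groups)) {
    gvars <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(gvars))
      stop("variable(s) in more than one group: ",
           paste(unique(gvars[duplicated(gvars)]), collapse = ", "),
           call. = FALSE)
    miss <- setdiff(vars, gvars)
    if (length(miss))
      stop("variable(s) not assigned to any group: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(variables = vars, edges = edges,
                 correlations = correlations, groups = groups,
                 exogenous = exogenous,
                 endogenous = setdiff(vars, exogenous),
                 topological_order = order),
            class = "path_spec")
}

# internal: topological order of vars under directed edges; error on cycles
topo_order <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(edges$target)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- vars[indeg == 0]
  edges_left <- edges
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    kids <- edges_left$target[edges_left$source == v]
    edges_left <- edges_left[edges_left$source != v, , drop = FALSE]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(out) != length(vars))
    stop("structural graph contains a directed cycle involving: ",
         paste(setdiff(vars, out), collapse = ", "), call. = FALSE)
  out
}

#' Read a path-model specification from a plain-text file
#'
#' One declaration per line, echoing common SEM model syntax:
#' \preformatted{
#'   # comment
#'   respiration ~ active_biomass + sir_efficiency + sir_range
#'   total_biomass ~~ active_biomass
#'   group: biomass = total_biomass, active_biomass
#' }
#'
#' @param path file path (or a character vector of lines via `text`).
#' @param text optional character vector of lines instead of a file.
#' @return a [path_spec()] object.
#' @export
read_path_spec <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  edges <- list(); corrs <- list(); groups <- list()
  for (ln in lines) {
    if (grepl("^group:", ln)) {
      body <- sub("^group:\\s*", "", ln)
      parts <- strsplit(body, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("bad group line: ", ln, call. = FALSE)
      groups[[trimws(parts[1])]] <-
        trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      if (length(parts) != 2) stop("bad correlation line: ", ln, call. = FALSE)
      corrs[[length(corrs) + 1L]] <- data.frame(a = parts[1], b = parts[2])
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~", fixed = TRUE)[[1]])
      if (length(parts) != 2) stop("bad equation line: ", ln, call. = FALSE)
      sources <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      edges[[length(edges) + 1L]] <-
        data.frame(source = sources, target = parts[1])
    } else stop("unparseable line: ", ln, call. = FALSE)
  }
  if (!length(edges)) stop("no equations found", call. = FALSE)
  path_spec(do.call(rbind, edges),
            correlations = if (length(corrs)) do.call(rbind, corrs) else NULL,
            groups = if (length(groups)) groups else NULL)
}

#' @export
print.path_spec <- function(x, ...) {
  cat("Path model:", length(x$variables), "variables,",
      nrow(x$edges), "directed edges,",
      if (is.null(x$correlations)) 0 else nrow(x$correlations),
      "correlation edges\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  invisible(x)
}
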
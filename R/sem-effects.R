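#' Standardized path table from a fit or from explicit coefficients
#'
#' The effect-decomposition functions operate on a "path table": one row
#' per directed edge with the standardized coefficient and (optionally) a
#' p-value and SE. `as_path_table` extracts it from a [fit_path_model()]
#' result, or validates a hand-built data.frame (e.g., a published set of
#' standardized coefficients), defaulting missing p-values to 0 (treated
#' as significant).
#'
#' @param x a `sem_fit` or a data.frame with columns `source`, `target`,
#'   `estimate` (standardized) and optionally `p`, `se`.
#' @return data.frame with columns `source`, `target`, `estimate`, `se`, `p`.
#' @export
as_path_table <- function(x) {
  if (inherits(x, "sem_fit")) {
    out <- data.frame(source = x$paths$source, target = x$paths$target,
                      estimate = x$paths$std_estimate,
                      se = x$paths$std_se, p = x$paths$p)
  } else {
    out <- as.data.frame(x)
    stopifnot(all(c("source", "target", "estimate") %in% names(out)))
    if (is.null(out$p)) out$p <- 0
    if (is.null(out$se)) out$se <- NA_real_
    out <- out[, c("source", "target", "estimate", "se", "p")]
  }
  if (anyDuplicated(out[c("source", "target")]))
    stop("duplicate directed edges in path table", call. = FALSE)
  out
}

#' Decompose standardized effects into direct, indirect and total
#'
#' For every ordered pair of variables: the direct effect is the
#' standardized coefficient on the edge (0 if absent); the indirect effect
#' is the sum, over all directed paths of length >= 2, of the product of
#' the standardized coefficients along the path; the total effect is their
#' sum, exactly. Paths are enumerated exhaustively over the DAG; the
#' matrix power series \eqn{\sum_{k \ge 2} B^k} gives the same indirect
#' effects and is available as [effect_matrix_series()] for cross-checking.
#'
#' A mediated path is flagged significant when every constituent direct
#' edge has `p < alpha`; `indirect_sig` sums only those paths, and
#' `indirect_abs_sig` sums their absolute products (the quantity used by
#' [group_effect_summary()]). Delta-method SEs per enumerated path are
#' included in the `paths` attribute when edge SEs are available.
#'
#' @param x a `sem_fit` or path table (see [as_path_table()]).
#' @param alpha per-edge significance level for the significance flags.
#' @return object of class `effect_decomposition`: data.frame with one row
#'   per ordered (source, target) pair connected by at least one path:
#'   `direct`, `indirect`, `total`, `direct_p`, `direct_sig`,
#'   `indirect_sig`, `indirect_abs_sig`, `n_paths`; attribute `paths`
#'   holds the per-path enumeration.
#' @examples
#' pt <- data.frame(source = c("A", "B"), target = c("B", "C"),
#'                  estimate = c(0.5, 0.4))
#' decompose_effects(pt)
#' @export
decompose_effects <- function(x, alpha = 0.05) {
  pt <- as_path_table(x)
  vars <- unique(c(pt$source, pt$target))
  p <- length(vars)
  # adjacency: children[[v]] = edges out of v
  topo_order(vars, pt[, c("source", "target")])  # errors on cycles
  idx <- split(seq_len(nrow(pt)), pt$source)

  # exhaustive path enumeration by depth-first search
  paths <- list()
  walk <- function(v0, v, prod, sig, se2rel, len, chain) {
    rows <- idx[[v]]
    for (r in rows) {
      e <- pt[r, ]
      pr <- prod * e$estimate
      sg <- sig && !is.na(e$p) && e$p < alpha
      s2 <- se2rel + if (is.na(e$se) || e$estimate == 0) NA_real_ else
        (e$se / e$estimate)^2
      ch <- c(chain, e$target)
      paths[[length(paths) + 1L]] <<- list(
        source = v0, target = e$target, length = len + 1L,
        product = pr, all_significant = sg,
        se = if (is.na(s2)) NA_real_ else abs(pr) * sqrt(s2),
        chain = paste(ch, collapse = "->"))
      walk(v0, e$target, pr, sg, s2, len + 1L, ch)
    }
  }
  for (v in vars) walk(v, v, 1, TRUE, 0, 0L, v)
  pd <- do.call(rbind, lapply(paths, function(q)
    data.frame(source = q$source, target = q$target, length = q$length,
               product = q$product, all_significant = q$all_significant,
               se = q$se, chain = q$chain)))

  agg <- stats::aggregate(
    cbind(indirect = ifelse(pd$length >= 2, pd$product, 0),
          indirect_sig = ifelse(pd$length >= 2 & pd$all_significant,
                                pd$product, 0),
          indirect_abs_sig = ifelse(pd$length >= 2 & pd$all_significant,
                                    abs(pd$product), 0),
          n_paths = 1L),
    by = list(source = pd$source, target = pd$target), FUN = sum)
  dir_idx <- match(paste(agg$source, agg$target),
                   paste(pt$source, pt$target))
  agg$direct <- ifelse(is.na(dir_idx), 0, pt$estimate[dir_idx])
  agg$direct_p <- ifelse(is.na(dir_idx), NA_real_, pt$p[dir_idx])
  agg$direct_sig <- !is.na(agg$direct_p) & agg$direct_p < alpha
  agg$total <- agg$direct + agg$indirect
  out <- agg[order(agg$source, agg$target),
             c("source", "target", "direct", "indirect", "total",
               "direct_p", "direct_sig", "indirect_sig",
               "indirect_abs_sig", "n_paths")]
  rownames(out) <- NULL
  attr(out, "paths") <- pd
  attr(out, "alpha") <- alpha
  attr(out, "variables") <- vars
  class(out) <- c("effect_decomposition", "data.frame")
  out
}

#' Indirect and total effects via the matrix power series
#'
#' Builds the standardized coefficient matrix `B` (with `B[t, s]` the
#' effect of `s` on `t`) and returns `direct = B`,
#' `indirect = sum_{k=2}^{p-1} B^k` and `total = direct + indirect`.
#' Used as the independent cross-check of the path-enumeration algorithm
#' in [decompose_effects()].
#'
#' @param x a `sem_fit` or path table.
#' @return list of three named matrices `direct`, `indirect`, `total`.
#' @export
effect_matrix_series <- function(x) {
  pt <- as_path_table(x)
  vars <- unique(c(pt$source, pt$target))
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  B[cbind(match(pt$target, vars), match(pt$source, vars))] <- pt$estimate
  indirect <- matrix(0, p, p, dimnames = list(vars, vars))
  Bk <- B
  for (k in seq(2, max(2, p - 1))) {
    Bk <- Bk %*% B
    indirect <- indirect + Bk
  }
  list(direct = B, indirect = indirect, total = B + indirect)
}

#' Summed absolute standardized effects of variable groups
#'
#' Summarizes the influence of a source group of variables on a target
#' (a variable or a whole group) by summing absolute standardized effects
#' over significant paths: the direct component sums `|estimate|` over
#' significant direct edges from group members to the target, and the
#' indirect component sums `|product|` over mediated paths whose
#' constituent edges are all significant. With `mode = "total"` the
#' significance filter is dropped.
#'
#' @param decomp an [decompose_effects()] result.
#' @param groups named list: group name -> character vector of variables
#'   (e.g., `spec$groups` from a [path_spec()]).
#' @param target target variable name or group name.
#' @param mode `"significant"` (default) or `"total"`.
#' @return data.frame with one row per source group: `group`, `direct`,
#'   `indirect`, `total` (all sums of absolute effects, non-negative).
#' @export
group_effect_summary <- function(decomp, groups, target,
                                 mode = c("significant", "total")) {
  mode <- match.arg(mode)
  stopifnot(inherits(decomp, "effect_decomposition"))
  if (is.null(groups) || !length(groups))
    stop("no groups supplied", call. = FALSE)
  tvars <- if (target %in% names(groups)) groups[[target]] else target
  unknown <- setdiff(tvars, attr(decomp, "variables"))
  if (length(unknown) && !target %in% names(groups))
    stop("unknown target '", target, "'", call. = FALSE)
  pd <- attr(decomp, "paths")
  rows <- lapply(names(groups), function(g) {
    gv <- setdiff(groups[[g]], tvars)
    sel <- pd$source %in% gv & pd$target %in% tvars
    if (mode == "significant") sel <- sel & pd$all_significant
    dsum <- sum(abs(pd$product[sel & pd$length == 1]))
    isum <- sum(abs(pd$product[sel & pd$length >= 2]))
    data.frame(group = g, direct = dsum, indirect = isum,
               total = dsum + isum)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
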
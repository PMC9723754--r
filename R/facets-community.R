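#' Rarefy a community count matrix to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, so
#' that every retained sample sums exactly to `depth`. Samples whose total
#' is below `depth` are dropped with a warning (set `drop_below = FALSE`
#' to fail hard instead), mirroring common amplicon practice.
#'
#' @param counts integer matrix of counts, taxa in rows, samples in columns.
#' @param depth target number of reads per sample.
#' @param seed integer seed; subsampling is deterministic given the seed.
#' @param drop_below drop samples with fewer than `depth` reads (default)
#'   or raise an error.
#' @return A count matrix with the same taxa and the retained samples, each
#'   column summing to `depth`.
#' @examples
#' m <- matrix(c(6L, 3L, 1L, 5L, 5L, 0L), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("a", "b")))
#' colSums(rarefy_counts(m, depth = 5, seed = 1))
#' @export
rarefy_counts <- function(counts, depth, seed = 1L, drop_below = TRUE) {
  counts <- as_count_matrix(counts)
  depth <- check_count(depth, "depth")
  totals <- colSums(counts)
  low <- totals < depth
  if (any(low)) {
    msg <- sprintf("%d sample(s) below depth %d dropped: %s",
                   sum(low), depth,
                   paste(colnames(counts)[low], collapse = ", "))
    if (!drop_below) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    counts <- counts[, !low, drop = FALSE]
    totals <- totals[!low]
  }
  if (ncol(counts) == 0L) return(counts)
  out <- counts
  set.seed(seed)
  for (j in seq_len(ncol(counts))) {
    cj <- counts[, j]
    if (totals[j] == depth) next  # already at depth, leave untouched
    reads <- rep.int(seq_along(cj), cj)
    keep <- sample(reads, depth, replace = FALSE)
    out[, j] <- tabulate(keep, nbins = length(cj))
  }
  storage.mode(out) <- "integer"
  out
}

#' Alpha-diversity indices of a community matrix
#'
#' Per sample: observed richness `S` (taxa with positive count), Shannon
#' diversity `H` (natural log), Pielou evenness `J = H / ln S` (0 when
#' `S = 1`), and dominance `G`, computed as Simpson dominance
#' \eqn{\sum p_i^2} (higher = more dominated).
#'
#' @param counts count matrix, taxa in rows, samples in columns; every
#'   sample must have a positive total.
#' @return data.frame with columns `sample`, `S`, `H`, `J`, `G`.
#' @examples
#' m <- matrix(c(5L, 3L, 2L), ncol = 1, dimnames = list(NULL, "s1"))
#' diversity_indices(m)
#' @export
diversity_indices <- function(counts) {
  counts <- as_count_matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    p <- x[x > 0] / totals[j]
    s <- length(p)
    h <- -sum(p * log(p))
    data.frame(sample = colnames(counts)[j],
               S = s,
               H = h,
               J = if (s <= 1) 0 else h / log(s),
               G = sum(p^2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# internal: validate/coerce a taxa-by-samples count matrix
as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts)))
    stop("sample identifiers must be unique", call. = FALSE)
  storage.mode(counts) <- "integer"
  counts
}
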
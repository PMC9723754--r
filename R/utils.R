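#' Shannon entropy and Pielou evenness of a non-negative vector
#'
#' Shannon entropy is \eqn{H = -\sum p_i \ln p_i} over the entries with
#' \eqn{p_i > 0} (natural log; \eqn{0 \ln 0 := 0}). Pielou evenness is
#' \eqn{J = H / \ln S} where \eqn{S} is the number of positive entries;
#' \eqn{J} is defined as 0 when \eqn{S \le 1} (the 0/0 limit of a
#' monodominant vector).
#'
#' @param x numeric vector of non-negative abundances (counts, biomasses,
#'   CO2 production rates, ...).
#' @return For `shannon_entropy`, the entropy in nats; for `pielou_evenness`,
#'   a value in `[0, 1]`, or `NA` if `x` sums to zero.
#' @examples
#' shannon_entropy(rep(1, 8))   # log(8)
#' pielou_evenness(c(1, 2, 3))
#' @export
shannon_entropy <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  tot <- sum(x, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  p <- x[x > 0 & !is.na(x)] / tot
  -sum(p * log(p))
}

#' @rdname shannon_entropy
#' @export
pielou_evenness <- function(x) {
  tot <- sum(x, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  s <- sum(x > 0, na.rm = TRUE)
  if (s <= 1) return(0)
  shannon_entropy(x) / log(s)
}

# internal: stop() with variable name in the message
abort_constant <- function(name) {
  stop(sprintf("variable '%s' is constant (zero standard deviation)", name),
       call. = FALSE)
}

# internal: check a numeric scalar count
check_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  as.integer(x)
}

# internal: derived integer seed (kept well below 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147480000)
}
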
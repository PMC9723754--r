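#' Functional-gene scores: catabolic-gene score and gene evenness
#'
#' Two summaries of a functional-gene abundance table. The catabolic-gene
#' score (`cata_score`) rescales each gene's abundance across samples and
#' sums the rescaled abundances of the catabolism-flagged genes. The gene
#' evenness (`fg_evenness`) is the Pielou evenness of each sample's raw
#' gene-abundance vector.
#'
#' Two scalings are offered. `"minmax"` (default) maps each gene to
#' `[0, 1]` across samples, so `cata_score` is bounded by the number of
#' catabolic genes; `"zscore"` centres and scales each gene to unit SD.
#' The scaling used is recorded in the `scaling` attribute of the result.
#' A gene constant across samples is scaled to 0 everywhere (with a
#' message) under either scheme.
#'
#' @param genes numeric matrix of gene abundances (copies per g soil),
#'   genes in rows, samples in columns; at least 2 samples.
#' @param catabolic logical vector flagging the catabolism-related genes,
#'   or a character vector of gene names; default all genes.
#' @param scaling `"minmax"` or `"zscore"`.
#' @return data.frame with columns `sample`, `cata_score`, `fg_evenness`;
#'   attribute `scaling` records the scheme used.
#' @export
gene_scores <- function(genes, catabolic = NULL,
                        scaling = c("minmax", "zscore")) {
  scaling <- match.arg(scaling)
  genes <- as.matrix(genes)
  if (any(genes < 0)) stop("gene abundances must be non-negative", call. = FALSE)
  if (ncol(genes) < 2)
    stop("scaling is across samples: need at least 2 samples", call. = FALSE)
  if (is.null(rownames(genes)))
    rownames(genes) <- paste0("gene", seq_len(nrow(genes)))
  if (is.null(colnames(genes)))
    colnames(genes) <- paste0("sample", seq_len(ncol(genes)))
  if (is.null(catabolic)) catabolic <- rep(TRUE, nrow(genes))
  if (is.character(catabolic)) catabolic <- rownames(genes) %in% catabolic
  stopifnot(length(catabolic) == nrow(genes))

  rng <- apply(genes, 1, function(x) diff(range(x)))
  if (any(rng == 0))
    message("constant gene column(s) scaled to 0: ",
            paste(rownames(genes)[rng == 0], collapse = ", "))
  scaled <- t(apply(genes, 1, function(x) {
    if (diff(range(x)) == 0) return(rep(0, length(x)))
    if (scaling == "minmax") (x - min(x)) / diff(range(x))
    else (x - mean(x)) / stats::sd(x)
  }))
  cata <- colSums(scaled[catabolic, , drop = FALSE])

  fg_eve <- apply(genes, 2, function(x) {
    if (sum(x) == 0) NA_real_ else pielou_evenness(x)
  })
  out <- data.frame(sample = colnames(genes), cata_score = cata,
                    fg_evenness = fg_eve, row.names = NULL)
  attr(out, "scaling") <- scaling
  out
}
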
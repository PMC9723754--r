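#' Default PLFA biomarker-to-group assignment
#'
#' A representative assignment of phospholipid fatty-acid biomarkers to
#' microbial groups: Gram-positive and Gram-negative bacterial markers,
#' general bacterial markers, fungal markers, and unspecific markers.
#' The `kingdom` column drives the bacteria-to-fungi ratio.
#'
#' @return data.frame with columns `marker`, `group`,
#'   `kingdom` (`"bacteria"`, `"fungi"` or `"other"`).
#' @export
plfa_marker_map <- function() {
  data.frame(
    marker = c("i15:0", "a15:0", "i16:0", "i17:0", "a17:0",
               "16:1w7", "cy17:0", "18:1w7", "cy19:0",
               "15:0", "17:0",
               "18:2w6,9", "18:1w9",
               "16:0", "18:0"),
    group = c(rep("gram_positive", 5), rep("gram_negative", 4),
              rep("general_bacteria", 2),
              rep("fungi", 2),
              rep("unspecific", 2)),
    kingdom = c(rep("bacteria", 11), rep("fungi", 2), rep("other", 2)),
    stringsAsFactors = FALSE
  )
}

#' Microbial biomass summaries from a PLFA marker table
#'
#' Total microbial biomass is the sum of all marker biomasses; the
#' bacteria-to-fungi ratio (B:F) is the sum of bacterial markers divided by
#' the sum of fungal markers. A sample with zero fungal biomass gets
#' `bf_ratio = NA` (flagged, not infinite).
#'
#' @param plfa numeric matrix of marker biomasses (nmol per g dry soil),
#'   markers in rows, samples in columns.
#' @param marker_map data.frame mapping each marker to a `kingdom`
#'   (see [plfa_marker_map()]); must cover every row of `plfa`.
#' @return data.frame with columns `sample`, `total_biomass`, `bf_ratio`.
#' @export
biomass_summary <- function(plfa, marker_map = plfa_marker_map()) {
  plfa <- as.matrix(plfa)
  if (any(plfa < 0)) stop("biomasses must be non-negative", call. = FALSE)
  if (is.null(rownames(plfa))) stop("plfa must have marker rownames", call. = FALSE)
  missing <- setdiff(rownames(plfa), marker_map$marker)
  if (length(missing))
    stop("markers not covered by the marker map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  kingdom <- marker_map$kingdom[match(rownames(plfa), marker_map$marker)]
  total <- colSums(plfa)
  bac <- colSums(plfa[kingdom == "bacteria", , drop = FALSE])
  fun <- colSums(plfa[kingdom == "fungi", , drop = FALSE])
  bf <- ifelse(fun > 0, bac / fun, NA_real_)
  if (any(fun == 0))
    warning("zero fungal biomass in sample(s): ",
            paste(colnames(plfa)[fun == 0], collapse = ", "),
            "; B:F set to NA", call. = FALSE)
  data.frame(sample = colnames(plfa), total_biomass = total, bf_ratio = bf,
             row.names = NULL)
}
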
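# Composite z-score indices: HSA21 gene-cluster polygenic scores and the MS3
# cytokine score.

#' Polygenic expression score over a gene list
#'
#' Per-sample sum of z-scores (relative to the reference group used when the
#' z-matrix was built) over the given genes. Samples missing any component are
#' not dropped: their score is the sum over available components and they are
#' flagged via a completeness fraction below 1.
#'
#' @param z A `zscore_matrix` (or plain z matrix).
#' @param genes Component gene/analyte ids; all must be present.
#' @param name Score name recorded in the output.
#' @return data.frame of class `composite_score`: sample_id, score, value,
#'   n_components, completeness, flagged.
#' @export
polygenic_score <- function(z, genes, name = "score") {
  zm <- as_z_matrix(z)
  missing_g <- setdiff(genes, rownames(zm))
  if (length(missing_g) > 0L) {
    stop("score component(s) absent from z matrix: ",
         paste(utils::head(missing_g, 10L), collapse = ", "), call. = FALSE)
  }
  sub <- zm[genes, , drop = FALSE]
  completeness <- colMeans(!is.na(sub))
  out <- data.frame(
    sample_id = colnames(zm),
    score = name,
    value = colSums(sub, na.rm = TRUE),
    n_components = length(genes),
    completeness = completeness,
    flagged = completeness < 1,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("composite_score", class(out))
  out
}

#' Select analytes for the MS3 cytokine score
#'
#' Analytes significantly elevated in MS3 relative to both euploid controls
#' and MS1: linear fold change above `fc_threshold` (i.e. `log2FC >
#' log2(fc_threshold)`; the default threshold of 1 means any elevation) and
#' `q < q_threshold` in BOTH contrasts. Output is ordered by ascending q in
#' the control contrast.
#'
#' @param diff_vs_controls,diff_vs_ms1 `differential_result` data.frames from
#'   [linear_diff()] for MS3-vs-controls and MS3-vs-MS1, covering the same
#'   analyte set.
#' @param fc_threshold Linear fold-change threshold; default 1.
#' @param q_threshold BH q threshold; default 0.1 (10\% FDR).
#' @return Character vector of selected analyte ids (possibly empty, with a
#'   warning).
#' @export
select_score_analytes <- function(diff_vs_controls, diff_vs_ms1,
                                  fc_threshold = 1, q_threshold = 0.1) {
  a <- diff_vs_controls
  b <- diff_vs_ms1
  if (!setequal(a$feature, b$feature)) {
    stop("contrasts cover different analyte sets", call. = FALSE)
  }
  b <- b[match(a$feature, b$feature), , drop = FALSE]
  lfc_thr <- log2(fc_threshold)
  sel <- !is.na(a$q) & !is.na(b$q) &
    a$log2FC > lfc_thr & b$log2FC > lfc_thr &
    a$q < q_threshold & b$q < q_threshold
  out <- a$feature[sel][order(a$q[sel])]
  if (length(out) == 0L) {
    warning("no analytes pass the selection rule", call. = FALSE)
  }
  out
}

#' MS3 cytokine score
#'
#' Per-sample sum of panel z-scores (relative to euploid controls) over the
#' selected analytes. Identical mechanics to [polygenic_score()].
#'
#' @param z A `zscore_matrix` of the cytokine panel.
#' @param analytes Selected analytes, e.g. from [select_score_analytes()].
#' @return A `composite_score` data.frame.
#' @export
cytokine_score <- function(z, analytes) {
  polygenic_score(z, analytes, name = "cytokine_score")
}
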
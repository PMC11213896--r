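# Ratio-based clinical indexes for detecting the inflammatory subtype (MS3):
# acute-phase analyte over lymphocyte measure, thresholded at a percentile of
# euploid controls.

#' Percentile cutoff from control values
#'
#' The `pct`-th percentile of the control distribution under the type-7
#' (linear interpolation) quantile convention. Requires at least `min_n`
#' controls for a stable cutoff.
#'
#' @param control_values Numeric vector of control ratios.
#' @param pct Percentile in `[0, 100]`; default 90.
#' @param min_n Minimum number of controls; default 10.
#' @return The cutoff value.
#' @export
percentile_cutoff <- function(control_values, pct = 90, min_n = 10L) {
  v <- control_values[!is.na(control_values)]
  if (length(v) < min_n) {
    stop("need >= ", min_n, " control values for a stable cutoff",
         call. = FALSE)
  }
  stats::quantile(v, pct / 100, type = 7, names = FALSE)
}

#' Define a ratio index
#'
#' @param name Index name.
#' @param num_layer,num_feature Layer and feature id of the numerator.
#' @param den_layer,den_feature Layer and feature id of the denominator.
#' @param pct Control percentile for the cutoff; default 90.
#' @return A `ratio_index` list.
#' @export
ratio_index <- function(name, num_layer, num_feature, den_layer, den_feature,
                        pct = 90) {
  structure(list(name = name, num_layer = num_layer,
                 num_feature = num_feature, den_layer = den_layer,
                 den_feature = den_feature, pct = pct),
            class = "ratio_index")
}

#' Default MS3 ratio indexes
#'
#' The four published-style indexes: CRP, IL-6 and SAA1 (broad plasma
#' proteomic panel) and the neutrophil fraction (immune-cell composition),
#' each over a lymphocyte measurement from the CBC. Ratios are
#' unit-heterogeneous (relative abundance over counts or percentages) and the
#' cutoffs are dataset-internal, never portable across datasets.
#'
#' @return List of four `ratio_index` objects.
#' @export
default_ratio_indexes <- function() {
  list(
    ratio_index("CRP/abs_lymphocytes", "somalike_proteome", "CRP",
                "cbc", "Lymphocytes_abs"),
    ratio_index("IL-6/pct_lymphocytes", "somalike_proteome", "IL-6",
                "cbc", "Lymphocytes_pct"),
    ratio_index("SAA1/abs_lymphocytes", "somalike_proteome", "SAA1",
                "cbc", "Lymphocytes_abs"),
    ratio_index("neutrophils/abs_lymphocytes", "cell_fractions", "Neutrophils",
                "cbc", "Lymphocytes_abs")
  )
}

#' Evaluate a ratio index against subtype truth
#'
#' Computes the per-sample ratio, derives the cutoff from euploid controls at
#' the index's percentile, calls trisomic samples positive when their ratio
#' exceeds the cutoff, and reports sensitivity (positives among MS3) and
#' specificity (negatives among non-MS3 trisomic samples). Samples with a
#' non-positive denominator are excluded with a message.
#'
#' @param idx A `ratio_index`.
#' @param layers Named list of feature x sample matrices.
#' @param truth Named character vector for trisomic samples: `"MS3"` or any
#'   other label; must cover every evaluated T21 sample.
#' @param controls Character vector of euploid control sample ids.
#' @return List of class `classifier_entry`: index, cutoff, ratios, calls,
#'   confusion counts, sensitivity, specificity.
#' @export
evaluate_index <- function(idx, layers, truth, controls) {
  stopifnot(inherits(idx, "ratio_index"))
  num_m <- layers[[idx$num_layer]]
  den_m <- layers[[idx$den_layer]]
  if (is.null(num_m) || is.null(den_m)) {
    stop("index layers missing from `layers`", call. = FALSE)
  }
  if (!(idx$num_feature %in% rownames(num_m)) ||
      !(idx$den_feature %in% rownames(den_m))) {
    stop("index feature(s) absent: ", idx$num_feature, " / ",
         idx$den_feature, call. = FALSE)
  }
  shared <- intersect(colnames(num_m), colnames(den_m))
  num <- num_m[idx$num_feature, shared]
  den <- den_m[idx$den_feature, shared]
  bad <- is.na(num) | is.na(den) | den <= 0
  if (any(bad)) {
    message("evaluate_index: excluding ", sum(bad),
            " sample(s) with missing or non-positive values")
  }
  ratio <- (num / den)[!bad]
  ctrl <- intersect(names(ratio), controls)
  cutoff <- percentile_cutoff(ratio[ctrl], pct = idx$pct)
  cases <- setdiff(names(ratio), controls)
  missing_truth <- setdiff(cases, names(truth))
  if (length(missing_truth) > 0L) {
    stop("truth label missing for sample(s): ",
         paste(utils::head(missing_truth, 5L), collapse = ", "), call. = FALSE)
  }
  call_pos <- ratio[cases] > cutoff
  is_ms3 <- truth[cases] == "MS3"
  tp <- sum(call_pos & is_ms3); fn <- sum(!call_pos & is_ms3)
  fp <- sum(call_pos & !is_ms3); tn <- sum(!call_pos & !is_ms3)
  structure(list(
    index = idx, cutoff = cutoff, ratios = ratio,
    calls = call_pos, truth_ms3 = is_ms3,
    confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  ), class = "classifier_entry")
}

#' Combine ratio indexes into a multi-index classifier
#'
#' Default rule `"all"`: a sample is called positive only if every component
#' index calls it positive (AND rule), which can only raise specificity and
#' lower sensitivity relative to each component -- this set-theoretic
#' monotonicity is asserted on every run. A `"majority"` rule is also
#' available.
#'
#' @param entries List of `classifier_entry` objects over the same samples.
#' @param rule `"all"` (AND) or `"majority"`.
#' @return A list of class `classifier_entry` for the combined rule (without
#'   per-index fields), plus `rule` and `components`.
#' @export
combine_indexes <- function(entries, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (length(entries) < 2L) stop("need >= 2 indexes", call. = FALSE)
  ids <- lapply(entries, function(e) sort(names(e$calls)))
  if (!all(vapply(ids[-1L], identical, TRUE, ids[[1L]]))) {
    stop("indexes cover different sample sets", call. = FALSE)
  }
  samp <- ids[[1L]]
  call_mat <- vapply(entries, function(e) e$calls[samp], logical(length(samp)))
  combined <- if (rule == "all") {
    rowSums(call_mat) == ncol(call_mat)
  } else {
    rowSums(call_mat) > ncol(call_mat) / 2
  }
  is_ms3 <- entries[[1L]]$truth_ms3[samp]
  tp <- sum(combined & is_ms3); fn <- sum(!combined & is_ms3)
  fp <- sum(combined & !is_ms3); tn <- sum(!combined & !is_ms3)
  out <- structure(list(
    rule = rule,
    components = vapply(entries, function(e) e$index$name, ""),
    calls = stats::setNames(combined, samp),
    truth_ms3 = is_ms3,
    confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  ), class = "classifier_entry")
  if (rule == "all") {
    # AND combination: specificity never below, sensitivity never above,
    # any component (exact set property)
    stopifnot(all(out$specificity >= vapply(entries, `[[`, 0, "specificity") -
                    1e-12),
              all(out$sensitivity <= vapply(entries, `[[`, 0, "sensitivity") +
                    1e-12))
  }
  out
}

#' Classifier report across indexes
#'
#' Convenience wrapper: evaluates each index, combines them with the AND rule,
#' and returns a tidy summary table plus the raw entries.
#'
#' @param indexes List of `ratio_index` objects;
#'   default [default_ratio_indexes()].
#' @inheritParams evaluate_index
#' @return List of class `classifier_report` with `entries`, `combined`, and
#'   `summary` (data.frame of sensitivity/specificity per index and combined).
#' @export
classifier_report <- function(layers, truth, controls,
                              indexes = default_ratio_indexes()) {
  entries <- lapply(indexes, evaluate_index, layers = layers, truth = truth,
                    controls = controls)
  combined <- combine_indexes(entries, rule = "all")
  summary <- data.frame(
    index = c(vapply(entries, function(e) e$index$name, ""), "combined_AND"),
    cutoff = c(vapply(entries, `[[`, 0, "cutoff"), NA_real_),
    sensitivity = c(vapply(entries, `[[`, 0, "sensitivity"),
                    combined$sensitivity),
    specificity = c(vapply(entries, `[[`, 0, "specificity"),
                    combined$specificity),
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries, combined = combined, summary = summary),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
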
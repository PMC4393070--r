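#' Classify each reference edge against a predicted network
#'
#' Per reference edge (s -> t, sign):
#' * `Consistent` — the prediction contains (s -> t) with the same sign;
#' * `Inconsistent` — not consistent, but the prediction contains the
#'   reversed edge (t -> s, either sign) or (s -> t) with the opposite sign
#'   (a misdirected or mis-signed recovery);
#' * `NotFound` — otherwise.
#'
#' Reference genes absent from the prediction's gene universe trigger a
#' warning and their edges evaluate as `NotFound`.
#'
#' @param pred Predicted [signed_network()].
#' @param ref Reference [signed_network()].
#' @param universe Optional character vector of genes the prediction could
#'   have drawn edges over; defaults to the genes appearing in `pred`.
#' @return Character vector of verdicts, one per reference edge, in `ref`
#'   row order.
#' @export
classify_edges <- function(pred, ref, universe = NULL) {
  validate_network(pred)
  validate_network(ref)
  if (is.null(universe)) universe <- union(pred$source, pred$target)
  absent <- setdiff(union(ref$source, ref$target), universe)
  if (length(absent)) {
    warning("reference gene(s) absent from prediction universe: ",
            paste(absent, collapse = ", "))
  }
  key <- function(s, t, g) paste(s, t, g, sep = "|")
  pred_signed <- key(pred$source, pred$target, pred$sign)
  pred_pairs <- paste(pred$source, pred$target, sep = "|")
  vapply(seq_len(nrow(ref)), function(i) {
    s <- ref$source[i]; t <- ref$target[i]; sg <- ref$sign[i]
    if (s %in% absent || t %in% absent) return("NotFound")
    if (key(s, t, sg) %in% pred_signed) return("Consistent")
    reversed <- paste(t, s, sep = "|") %in% pred_pairs
    wrong_sign <- key(s, t, setdiff(c("activator", "repressor"), sg)) %in%
      pred_signed
    if (reversed || wrong_sign) return("Inconsistent")
    "NotFound"
  }, character(1L))
}

#' Confusion counts from per-reference-edge verdicts
#'
#' `tp` = consistent edges, `fp` = inconsistent (misdirected/mis-signed)
#' recoveries, `fn` = everything else, so `tp + fn` always equals the
#' reference edge count.  Predicted edges between pairs absent from the
#' reference are not counted here (see [evaluate_network()]'s `spurious`).
#'
#' @param verdicts Character vector over all reference edges.
#' @return List `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(verdicts) {
  stopifnot(all(verdicts %in% c("Consistent", "Inconsistent", "NotFound")))
  tp <- sum(verdicts == "Consistent")
  fp <- sum(verdicts == "Inconsistent")
  list(tp = tp, fp = fp, fn = length(verdicts) - tp)
}

#' Sensitivity (recall) of edge recovery
#' @param tp,fn Nonnegative counts.
#' @return `tp / (tp + fn)`, or 0 when the denominator is 0.
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn == 0) 0 else tp / (tp + fn)
}

#' Precision of edge recovery
#' @param tp,fp Nonnegative counts.
#' @return `tp / (tp + fp)`, or 0 when the denominator is 0.
#' @export
precision <- function(tp, fp) {
  if (tp + fp == 0) 0 else tp / (tp + fp)
}

#' Weighted harmonic F-score
#'
#' `1 / (alpha / precision + (1 - alpha) / sensitivity)`; with the default
#' `alpha = 0.5` this is the ordinary harmonic mean `2PS / (P + S)`.  Returns
#' 0 when either input is 0.
#'
#' @param precision,sensitivity Values in \[0, 1\].
#' @param alpha Weight in (0, 1).
#' @return F-score in \[0, 1\].
#' @export
f_score <- function(precision, sensitivity, alpha = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (precision == 0 || sensitivity == 0) return(0)
  1 / (alpha / precision + (1 - alpha) / sensitivity)
}

#' Evaluate a predicted network against a signed reference
#'
#' @param pred Predicted [signed_network()].
#' @param ref Reference [signed_network()].
#' @param alpha F-score weighting factor.
#' @param universe Optional gene universe (see [classify_edges()]).
#' @return List `tp`, `fp`, `fn`, `sensitivity`, `precision`, `f_score`,
#'   `verdicts` (per reference edge), and `spurious` (count of predicted
#'   edges between ordered pairs that never appear in the reference).
#' @export
evaluate_network <- function(pred, ref, alpha = 0.5, universe = NULL) {
  verdicts <- classify_edges(pred, ref, universe)
  cc <- confusion_counts(verdicts)
  ref_pairs <- unique(paste(ref$source, ref$target, sep = "|"))
  pred_pairs <- paste(pred$source, pred$target, sep = "|")
  sens <- sensitivity(cc$tp, cc$fn)
  prec <- precision(cc$tp, cc$fp)
  list(tp = cc$tp, fp = cc$fp, fn = cc$fn,
       sensitivity = sens, precision = prec,
       f_score = f_score(prec, sens, alpha),
       verdicts = verdicts,
       spurious = sum(!(pred_pairs %in% ref_pairs)))
}

#' Packaged signed reference network for the yeast cell-cycle demonstration
#'
#' The KEGG-derived set of 33 experimentally supported signed interactions
#' among 12 core yeast cell-cycle regulators (cyclins, CDC28, the SBF/MBF
#' transcription-factor subunits, SIC01, CDC20 and CDC06), shipped as a SIF
#' fixture.
#'
#' @return A [signed_network()] with 33 edges over 12 genes.
#' @export
reference_network <- function() {
  read_network(system.file("extdata", "kegg_cellcycle_reference.sif",
                           package = "fuzzygrn", mustWork = TRUE))
}

#' Packaged per-edge verdicts of the neuro-fuzzy method on the reference
#'
#' Published per-reference-edge verdicts (Consistent / Inconsistent /
#' NotFound) of the rule-based neuro-fuzzy pipeline on the 33-edge yeast
#' cell-cycle reference, used as a worked evaluation example.
#'
#' @return Data frame with columns `source`, `target`, `sign`, `verdict`,
#'   one row per reference edge.
#' @export
reference_verdicts <- function() {
  utils::read.delim(
    system.file("extdata", "reference_verdicts_neurofuzzy.tsv",
                package = "fuzzygrn", mustWork = TRUE),
    stringsAsFactors = FALSE)
}
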
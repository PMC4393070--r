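#' Canonicalize the rules of a trained model
#'
#' Rewrites each rule as a full-length label vector over all N genes: the
#' antecedent labels keep their gene positions and the consequent label is
#' inserted at the target gene's own position.  After canonicalization the
#' rules of all per-gene networks live in one common gene order and can be
#' compared directly.
#'
#' @param model A trained `rbnfn`.
#' @return List with `vectors` (rules x N integer label matrix, columns named
#'   by gene) and `weights` (learned weight per rule).
#' @export
canonicalize <- function(model) {
  stopifnot(inherits(model, "rbnfn"))
  rb <- model$rulebase
  if (is.null(rb$weights)) stop("model has no trained weights")
  n <- length(model$genes)
  k <- nrow(rb$antecedents)
  vectors <- matrix(NA_integer_, k, n, dimnames = list(NULL, model$genes))
  vectors[, -model$target_index] <- rb$antecedents
  vectors[, model$target_index] <- rb$consequents
  list(vectors = vectors, weights = rb$weights)
}

#' Group canonical rules across all per-gene networks
#'
#' Canonical rules are grouped by exact label-vector equality.  Each group is
#' the table of network effects on one shared rule: the map from network
#' (target gene) to the weight that network learned for the rule.  Groups are
#' returned in lexicographic label-vector order for determinism.
#'
#' @param models List of trained `rbnfn` models over a common gene set.
#' @return List of groups, each `list(rule = integer label vector,
#'   weights = named numeric vector keyed by network id)`.
#' @export
build_nesr <- function(models) {
  stopifnot(length(models) >= 1L)
  genes <- models[[1L]]$genes
  for (m in models) {
    if (!identical(m$genes, genes)) stop("models disagree on the gene set")
    if (!identical(unclass(m$mf), unclass(models[[1L]]$mf))) {
      stop("models disagree on membership-function parameters")
    }
  }
  rule_vecs <- list()
  net_ids <- character()
  weights <- numeric()
  for (m in models) {
    can <- canonicalize(m)
    rule_vecs <- c(rule_vecs, asplit(can$vectors, 1L))
    net_ids <- c(net_ids, rep(m$target_gene, length(can$weights)))
    weights <- c(weights, can$weights)
  }
  keys <- vapply(rule_vecs, paste, character(1L), collapse = ",")
  groups <- lapply(sort(unique(keys)), function(kk) {
    idx <- which(keys == kk)
    w <- weights[idx]
    names(w) <- net_ids[idx]
    rule <- as.integer(rule_vecs[[idx[1L]]])
    names(rule) <- genes
    list(rule = rule, weights = w[order(match(names(w), genes))])
  })
  groups
}

#' Effectivity threshold of one network
#'
#' The per-network cutoff deciding whether a rule meaningfully affects the
#' network's output gene, defined as the average of the network's rule
#' weights.  The default `abs` mode averages weight magnitudes, so the
#' threshold is always nonnegative and "effective" keeps its above-average
#' meaning even when weights carry mixed signs; `literal` mode averages the
#' signed weights.
#'
#' @param model A trained `rbnfn`.
#' @param mode `"abs"` (default) or `"literal"`.
#' @return Scalar threshold.
#' @export
effectivity_threshold <- function(model, mode = c("abs", "literal")) {
  mode <- match.arg(mode)
  w <- model$rulebase$weights
  if (is.null(w) || length(w) == 0L) stop("model has an empty rule base")
  if (mode == "abs") mean(abs(w)) else mean(w)
}

# Named vector of thresholds, one per model, in gene order.
effectivity_thresholds <- function(models, mode = c("abs", "literal")) {
  mode <- match.arg(mode)
  vapply(models, effectivity_threshold, numeric(1L), mode = mode)
}

#' Effectivity symbol of a weight against a threshold
#'
#' Ternary code: 0 if `|w| < T` (no meaningful effect), +1 if `|w| > T` and
#' `w > 0`, -1 if `|w| > T` and `w < 0`.  The boundary `|w| = T` maps to 0.
#' Vectorized over `w`.
#'
#' @param w Weight(s).
#' @param threshold Nonnegative threshold.
#' @return Integer(s) in \{-1, 0, +1\}.
#' @export
compute_es <- function(w, threshold) {
  if (!all(is.finite(threshold))) stop("threshold must be finite")
  as.integer(ifelse(abs(w) > threshold, sign(w), 0))
}

#' Effectivity-symbol matrices for all shared rules
#'
#' Replaces each shared rule's per-network weights by effectivity symbols.
#' Networks in which the rule never arose carry no evidence of effect and get
#' symbol 0, so every rule is scored against all N networks.
#'
#' @param nesr Groups from [build_nesr()].
#' @param thresholds Named per-network thresholds (names = gene ids, in gene
#'   order), e.g. from `effectivity_thresholds()`.
#' @return List, one per rule: `list(rule, es)` with `es` a named integer
#'   vector over all networks.
#' @export
build_es_matrices <- function(nesr, thresholds) {
  genes <- names(thresholds)
  lapply(nesr, function(grp) {
    if (!all(names(grp$weights) %in% genes)) {
      stop("thresholds do not cover all networks")
    }
    es <- stats::setNames(integer(length(genes)), genes)
    es[names(grp$weights)] <-
      compute_es(grp$weights, thresholds[names(grp$weights)])
    list(rule = grp$rule, es = es)
  })
}
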
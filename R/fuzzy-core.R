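#' Gaussian membership-function parameters
#'
#' Three linguistic labels (Low/Medium/High) by default, with centers
#' 0.2/0.5/0.8 spread evenly over the normalized \[0, 1\] expression scale and
#' a shared variance of 0.25.  The variance is the denominator of the Gaussian
#' exponent (sigma^2), so the default corresponds to sigma = 0.5.
#'
#' @param centers Strictly increasing label centers within \[0, 1\].
#' @param variance Positive variance shared by all labels.
#' @param labels Label names, one per center.
#' @return An object of class `mf_params`.
#' @export
mf_params <- function(centers = c(0.2, 0.5, 0.8), variance = 0.25,
                      labels = c("Low", "Medium", "High")) {
  if (length(centers) < 2L) stop("need at least 2 label centers")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  if (any(centers < 0 | centers > 1)) stop("centers must lie in [0, 1]")
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0) {
    stop("variance must be a single positive number")
  }
  if (length(labels) != length(centers)) stop("one label per center")
  structure(list(centers = as.numeric(centers), variance = as.numeric(variance),
                 labels = as.character(labels)),
            class = "mf_params")
}

#' Gaussian membership degree
#'
#' `exp(-(x - center)^2 / variance)`: 1 exactly at the center, decaying
#' symmetrically on both sides, never reaching 0.
#'
#' @param x Normalized value(s).
#' @param center Label center.
#' @param variance Positive variance (sigma^2).
#' @return Degree(s) in (0, 1].
#' @export
gaussian_membership <- function(x, center, variance) {
  if (any(variance <= 0)) stop("variance must be positive")
  exp(-(x - center)^2 / variance)
}

#' Fuzzify a normalized expression matrix
#'
#' Evaluates every gene/time-point value against all membership functions.
#'
#' @param nm Normalized matrix (entries in \[0, 1\], gene rownames).
#' @param p [mf_params()].
#' @return A 3-d array `genes x time points x labels` of degrees in (0, 1].
#' @export
fuzzify <- function(nm, p = mf_params()) {
  stopifnot(inherits(p, "mf_params"))
  deg <- vapply(p$centers,
                function(ctr) gaussian_membership(nm, ctr, p$variance),
                matrix(0, nrow(nm), ncol(nm)))
  dimnames(deg) <- list(rownames(nm), colnames(nm), p$labels)
  deg
}

#' Dominant linguistic label of a degree vector
#'
#' Index of the maximal membership degree; exact ties go to the lowest-index
#' (lowest-center) label, which makes the two equidistance points of the
#' default configuration (0.35 and 0.65) deterministic.
#'
#' @param degrees Per-label membership degrees.
#' @return Integer label index.
#' @export
dominant_label <- function(degrees) {
  which.max(degrees)
}

# Matrix of dominant label indices (genes x time points) from a membership
# tensor.  which.max over the label margin keeps the lowest-index tie-break.
dominant_labels <- function(mt) {
  apply(mt, c(1L, 2L), which.max)
}

# Build a rule base from per-time-point dominant labels.
# ant_labels: inputs x samples integer matrix; cons_labels: integer vector per
# sample.  One candidate rule per sample; candidates sharing an antecedent are
# merged, the merged consequent being the majority consequent among the
# occurrences (first-seen wins ties) and the support the occurrence count.
rulebase_from_labels <- function(ant_labels, cons_labels,
                                 target_gene, input_genes) {
  n_samples <- ncol(ant_labels)
  stopifnot(length(cons_labels) == n_samples, n_samples >= 1L)
  keys <- apply(ant_labels, 2L, paste, collapse = ",")
  first_seen <- !duplicated(keys)
  uniq_keys <- keys[first_seen]
  antecedents <- t(ant_labels[, first_seen, drop = FALSE])
  consequents <- integer(length(uniq_keys))
  support <- integer(length(uniq_keys))
  for (r in seq_along(uniq_keys)) {
    occ <- cons_labels[keys == uniq_keys[r]]
    support[r] <- length(occ)
    counts <- vapply(unique(occ), function(l) sum(occ == l), integer(1L))
    consequents[r] <- unique(occ)[which.max(counts)]
  }
  structure(list(target_gene = target_gene, input_genes = input_genes,
                 antecedents = antecedents, consequents = consequents,
                 support = support, weights = NULL),
            class = "rulebase")
}

#' Build the rule base for one target gene
#'
#' Each training time point contributes a candidate IF-THEN rule whose
#' antecedent is the dominant label of every input gene and whose consequent
#' is the dominant label of the target gene (optionally `lag` steps ahead).
#' Candidates with identical antecedents are merged so the rule base holds no
#' redundant rules; the rule count therefore never exceeds the number of
#' training samples.
#'
#' @param mt Membership tensor from [fuzzify()].
#' @param target_index Row index of the target gene.
#' @param lag Nonnegative integer: inputs at time t predict the target at
#'   time t + lag (default 0, contemporaneous).
#' @return A `rulebase` object (antecedent label matrix, consequent labels,
#'   supports; weights unset until training).
#' @export
build_rulebase <- function(mt, target_index, lag = 0L) {
  lag <- as.integer(lag)
  n_time <- dim(mt)[2L]
  if (lag < 0L || lag >= n_time) stop("lag must be in [0, n_timepoints - 1]")
  labels <- dominant_labels(mt)
  in_cols <- seq_len(n_time - lag)
  genes <- dimnames(mt)[[1L]]
  rulebase_from_labels(
    ant_labels = labels[-target_index, in_cols, drop = FALSE],
    cons_labels = labels[target_index, in_cols + lag],
    target_gene = genes[target_index],
    input_genes = genes[-target_index])
}

#' Firing strength of a rule on one sample
#'
#' Product T-norm over input genes of the Gaussian membership of the sample
#' value in the rule's label for that gene.
#'
#' @param rule_labels Integer label index per input gene.
#' @param sample Normalized value per input gene (same length/order).
#' @param p [mf_params()].
#' @return Strength in (0, 1].
#' @export
firing_strength <- function(rule_labels, sample, p = mf_params()) {
  if (length(rule_labels) != length(sample)) {
    stop("sample length must match antecedent length")
  }
  prod(gaussian_membership(sample, p$centers[rule_labels], p$variance))
}

# samples x rules matrix of raw firing strengths; samples given as an
# inputs x samples matrix of normalized values.
firing_matrix <- function(rb, samples, p) {
  n_s <- ncol(samples)
  strengths <- vapply(seq_len(nrow(rb$antecedents)), function(r) {
    labs <- rb$antecedents[r, ]
    exp(-colSums((samples - p$centers[labs])^2) / p$variance)
  }, numeric(n_s))
  matrix(strengths, nrow = n_s)
}

#' Normalize rule firing strengths to firing powers
#'
#' Divides each strength by the total so the powers form a probability
#' simplex (sum exactly 1).  Errors on an all-zero total, which cannot occur
#' analytically with Gaussian memberships but guards numeric underflow.
#'
#' @param strengths Positive strengths, one per rule.
#' @return Vector summing to 1.
#' @export
normalize_firing <- function(strengths) {
  if (length(strengths) < 1L) stop("need at least one rule")
  total <- sum(strengths)
  if (total <= 0) stop("total firing strength underflowed to zero")
  strengths / total
}

#' Defuzzify normalized firing powers with singleton weights
#'
#' The network output is the weighted sum of the normalized firing powers,
#' the rule weights acting as singleton consequents.
#'
#' @param powers Simplex vector from [normalize_firing()].
#' @param weights Learned weight per rule.
#' @return Scalar prediction.
#' @export
defuzzify <- function(powers, weights) {
  if (length(powers) != length(weights)) {
    stop("powers and weights must have equal length")
  }
  sum(powers * weights)
}
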
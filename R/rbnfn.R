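#' Train one rule-based neuro-fuzzy network
#'
#' Builds the rule base for `target` from the normalized matrix (all other
#' genes as inputs), forms the design matrix of normalized firing powers
#' (samples x rules), and learns the singleton rule weights by least squares:
#' `argmin ||Dw - y||^2 + ridge ||w||^2`.  With `ridge = 0` the minimum-norm
#' solution is taken via the Moore-Penrose pseudoinverse, which keeps the fit
#' defined when the design is collinear — the typical regime for short
#' microarray series.
#'
#' @param nm Normalized expression matrix (rows = genes).
#' @param target Target gene id.
#' @param p [mf_params()].
#' @param ridge Nonnegative ridge penalty (default 0).
#' @param lag Nonnegative lag: inputs at t predict the target at t + lag
#'   (default 0, contemporaneous, matching the per-time-point rule tables).
#' @return An object of class `rbnfn`: gene ids, trained `rulebase` (weights
#'   filled), MF parameters, and the training mean-squared error.
#' @export
train_rbnfn <- function(nm, target, p = mf_params(), ridge = 0, lag = 0L) {
  genes <- rownames(nm)
  target_index <- match(target, genes)
  if (is.na(target_index)) stop("unknown target gene: ", target)
  if (ncol(nm) < 2L) stop("need at least 2 time points")
  if (ridge < 0) stop("ridge must be nonnegative")
  mt <- fuzzify(nm, p)
  rb <- build_rulebase(mt, target_index, lag = lag)
  in_cols <- seq_len(ncol(nm) - lag)
  samples <- nm[-target_index, in_cols, drop = FALSE]
  y <- nm[target_index, in_cols + lag]
  D <- design_matrix(rb, samples, p)
  w <- ls_weights(D, y, ridge)
  rb$weights <- as.numeric(w)
  fitted <- as.numeric(D %*% w)
  structure(list(target_gene = genes[target_index], input_genes = genes[-target_index],
                 genes = genes, target_index = target_index,
                 rulebase = rb, mf = p, ridge = ridge, lag = as.integer(lag),
                 training_mse = mse(fitted, y)),
            class = "rbnfn")
}

# samples x rules design matrix of normalized firing powers.
design_matrix <- function(rb, samples, p) {
  strengths <- firing_matrix(rb, samples, p)
  totals <- rowSums(strengths)
  if (any(totals <= 0)) stop("total firing strength underflowed to zero")
  strengths / totals
}

# Least-squares weights: ridge-regularized normal equations when ridge > 0,
# minimum-norm pseudoinverse solution otherwise.
ls_weights <- function(D, y, ridge = 0) {
  if (ridge > 0) {
    solve(crossprod(D) + diag(ridge, ncol(D)), crossprod(D, y))
  } else {
    MASS::ginv(D) %*% y
  }
}

#' Predict a target gene's normalized series
#'
#' For each time point, computes the rule firing strengths on the input
#' genes' values, normalizes them, and defuzzifies with the learned weights.
#'
#' @param object A trained `rbnfn` model.
#' @param nm Normalized matrix containing all input genes (rows may be a
#'   superset; matched by gene id).
#' @param ... Ignored.
#' @return Numeric vector of predictions, one per input sample (time points
#'   `1 .. T - lag`, aligned to target positions `1 + lag .. T`).
#' @export
predict.rbnfn <- function(object, nm, ...) {
  missing_in <- setdiff(object$input_genes, rownames(nm))
  if (length(missing_in)) {
    stop("input gene(s) absent from matrix: ", paste(missing_in, collapse = ", "))
  }
  in_cols <- seq_len(ncol(nm) - object$lag)
  samples <- nm[object$input_genes, in_cols, drop = FALSE]
  D <- design_matrix(object$rulebase, samples, object$mf)
  as.numeric(D %*% object$rulebase$weights)
}

#' Mean squared error between two series
#'
#' @param predicted,measured Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop("series lengths differ (", length(predicted), " vs ",
         length(measured), ")")
  }
  if (length(predicted) < 1L) stop("need at least one sample")
  mean((predicted - measured)^2)
}

#' Train one model per gene
#'
#' Builds N independent models: in each, one gene is the output and all
#' remaining genes are the inputs.
#'
#' @inheritParams train_rbnfn
#' @return Named list of `rbnfn` models in gene (row) order.
#' @export
train_all <- function(nm, p = mf_params(), ridge = 0, lag = 0L) {
  if (nrow(nm) < 2L) stop("need at least 2 genes")
  models <- lapply(rownames(nm), function(g) train_rbnfn(nm, g, p, ridge, lag))
  names(models) <- rownames(nm)
  models
}

#' @export
print.rbnfn <- function(x, ...) {
  cat("Rule-based neuro-fuzzy network for gene", x$target_gene, "\n")
  cat("  inputs:", length(x$input_genes), "genes;",
      nrow(x$rulebase$antecedents), "rules; training MSE",
      format(x$training_mse, digits = 4), "\n")
  invisible(x)
}
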
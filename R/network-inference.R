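#' Extract directed connections from one effectivity-symbol vector
#'
#' For every ordered gene pair (i, p), i != p: if the rule shows no effect in
#' gene i's own network (`es[i] == 0`) but does show an effect in gene p's
#' network (`es[p] != 0`), gene i is connected to gene p — as an activator
#' when `es[p] == +1`, as a repressor when `es[p] == -1`.  A rule therefore
#' yields exactly (#zeros x #nonzeros) directed pairs.
#'
#' @param es Named integer vector in \{-1, 0, +1\}, one entry per network.
#' @return List with two 2-column character matrices, `activators` and
#'   `repressors` (columns source, target).
#' @export
extract_connections <- function(es) {
  genes <- names(es)
  if (is.null(genes)) genes <- as.character(seq_along(es))
  zeros <- which(es == 0L)
  make_pairs <- function(targets) {
    if (length(zeros) == 0L || length(targets) == 0L) {
      return(matrix(character(), 0L, 2L,
                    dimnames = list(NULL, c("source", "target"))))
    }
    cbind(source = rep(genes[zeros], times = length(targets)),
          target = rep(genes[targets], each = length(zeros)))
  }
  list(activators = make_pairs(which(es == 1L)),
       repressors = make_pairs(which(es == -1L)))
}

#' Accumulate activator and repressor criterion matrices
#'
#' Counts, over all rules, how many rules' connection sets contain an
#' activator (resp. repressor) connection for each ordered gene pair.
#'
#' @param conns List of connection sets from [extract_connections()].
#' @param genes Gene universe (row/column order of the result).
#' @return List of two N x N integer matrices `AC` and `RC` with zero
#'   diagonals and gene-id dimnames.
#' @export
accumulate_criteria <- function(conns, genes) {
  n <- length(genes)
  AC <- RC <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (cs in conns) {
    if (nrow(cs$activators)) {
      idx <- cbind(match(cs$activators[, 1L], genes),
                   match(cs$activators[, 2L], genes))
      AC[idx] <- AC[idx] + 1L
    }
    if (nrow(cs$repressors)) {
      idx <- cbind(match(cs$repressors[, 1L], genes),
                   match(cs$repressors[, 2L], genes))
      RC[idx] <- RC[idx] + 1L
    }
  }
  list(AC = AC, RC = RC)
}

#' Net interaction matrix
#'
#' Pairwise subtraction of a criterion matrix: `net[i, p] = C[i, p] - C[p, i]`.
#' Antisymmetric by construction.
#'
#' @param C Square criterion matrix with zero diagonal.
#' @return Antisymmetric matrix of the same shape.
#' @export
net_interaction <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (any(diag(C) != 0)) stop("criterion matrix must have a zero diagonal")
  C - t(C)
}

#' Final signed network from net interaction matrices
#'
#' Emits an activator edge i -> p with score `netAC[i, p]` whenever that net
#' count reaches `min_score` (default 1, i.e. strictly positive), and
#' likewise repressor edges from `netRC`.  Exact ties (net count 0) yield no
#' edge.  A pair may carry both an activator and a repressor edge, since the
#' two evidence channels are accumulated separately; `dominant_sign = TRUE`
#' keeps only the larger-score sign for such pairs.
#'
#' @param netAC,netRC Antisymmetric matrices from [net_interaction()].
#' @param min_score Minimum net count for an edge (positive integer).
#' @param dominant_sign Keep only the stronger sign per ordered pair.
#' @return A [signed_network()] data frame.
#' @export
finalize_network <- function(netAC, netRC, min_score = 1L,
                             dominant_sign = FALSE) {
  stopifnot(identical(dim(netAC), dim(netRC)))
  if (min_score < 1L) stop("min_score must be a positive integer")
  genes <- rownames(netAC)
  if (dominant_sign) {
    act_keep <- netAC >= pmax(netRC, 0)  # ties keep activator
    netAC <- ifelse(act_keep, netAC, 0)
    netRC <- ifelse(act_keep, 0, netRC)
  }
  edges_of <- function(net, sign) {
    idx <- which(net >= min_score, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(source = genes[idx[, 1L]], target = genes[idx[, 2L]],
               sign = sign, score = as.integer(net[idx]),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edges_of(netAC, "activator"), edges_of(netRC, "repressor"))
  if (is.null(edges)) return(signed_network())
  signed_network(edges$source, edges$target, edges$sign, edges$score)
}

#' Infer a signed gene regulatory network from expression data
#'
#' Runs the whole pipeline on a raw expression matrix: KNN imputation of any
#' missing values, per-gene min-max normalization, training of one
#' neuro-fuzzy model per gene, rule canonicalization and cross-network
#' grouping, effectivity thresholding, connection extraction, and
#' accumulation into the final signed directed network.
#'
#' @param expr Raw expression matrix (genes x time points, `NA` allowed).
#' @param config [pipeline_config()] with the tunable parameters.
#' @return List of class `grn_inference`: `network` (a [signed_network()]),
#'   `models`, `thresholds`, `criteria` (`AC`/`RC` count matrices), and a
#'   `report` list (per-gene rule counts, training MSEs, config echo).
#' @export
infer_network <- function(expr, config = pipeline_config()) {
  validate_expression(expr)
  if (anyNA(expr)) expr <- impute_knn(expr, k = config$knn_k)
  nm <- normalize_minmax(expr)
  p <- mf_params(config$centers, config$variance, config$labels)
  models <- train_all(nm, p, ridge = config$ridge, lag = config$lag)
  nesr <- build_nesr(models)
  thresholds <- effectivity_thresholds(models, mode = config$threshold_mode)
  es_mats <- build_es_matrices(nesr, thresholds)
  conns <- lapply(es_mats, function(e) extract_connections(e$es))
  crit <- accumulate_criteria(conns, rownames(nm))
  network <- finalize_network(net_interaction(crit$AC),
                              net_interaction(crit$RC),
                              min_score = config$min_score,
                              dominant_sign = config$dominant_sign)
  report <- list(
    n_genes = nrow(nm),
    n_timepoints = ncol(nm),
    n_shared_rules = length(nesr),
    n_edges = nrow(network),
    rule_counts = vapply(models, function(m) nrow(m$rulebase$antecedents),
                         integer(1L)),
    training_mse = vapply(models, function(m) m$training_mse, numeric(1L)),
    thresholds = thresholds,
    config = unclass(config))
  structure(list(network = network, models = models, thresholds = thresholds,
                 criteria = crit, report = report),
            class = "grn_inference")
}

#' @export
print.grn_inference <- function(x, ...) {
  r <- x$report
  cat("Neuro-fuzzy GRN inference:", r$n_genes, "genes,", r$n_timepoints,
      "time points\n")
  cat("  shared rules:", r$n_shared_rules, "; inferred edges:", r$n_edges,
      "(", sum(x$network$sign == "activator"), "activator /",
      sum(x$network$sign == "repressor"), "repressor )\n")
  invisible(x)
}
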
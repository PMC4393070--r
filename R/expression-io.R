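#' Read a gene-by-time-point expression matrix
#'
#' Parses a delimited text file with a header row (`gene<delim>T1..Tn`), one
#' gene per row, first column the gene identifier and the remaining columns
#' numeric expression values.  Empty cells and the tokens `NA` / `NaN`
#' (case-insensitive) are treated as missing and stored as `NA`.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, `"\t"` (default) or `","`.
#' @return A numeric matrix, genes as rows (rownames = gene ids), time points
#'   as columns (colnames = header labels), `NA` marking missing entries.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) {
    stop("expression file needs a header and at least 2 gene rows: ", path)
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged row in expression file at line ", bad,
         " (expected ", widths[1L], " fields, found ", widths[bad], ")")
  }
  if (widths[1L] < 3L) stop("need at least 2 time-point columns")
  header <- fields[[1L]]
  body <- fields[-1L]
  gene_ids <- trimws(vapply(body, `[`, character(1L), 1L))
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  cells <- t(vapply(body, function(f) trimws(f[-1L]),
                    character(widths[1L] - 1L)))
  is_na_token <- cells == "" | tolower(cells) %in% c("na", "nan")
  parsed <- suppressWarnings(as.numeric(cells))
  bad_cell <- !is_na_token & is.na(parsed)
  if (any(bad_cell)) {
    idx <- which(bad_cell, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", cells[bad_cell][1L], "' for gene ",
         gene_ids[idx[1L]], " at column ", idx[2L])
  }
  parsed[is_na_token] <- NA_real_
  m <- matrix(parsed, nrow = length(gene_ids),
              dimnames = list(gene_ids, trimws(header[-1L])))
  validate_expression(m)
  m
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: header row `gene<delim>labels`, missing
#' entries written as `NA`.
#'
#' @param m Expression matrix with gene rownames.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  validate_expression(m)
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("T", seq_len(ncol(m)))
  header <- paste(c("gene", labels), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    vals <- ifelse(is.na(m[i, ]), "NA", format(m[i, ], trim = TRUE, digits = 15))
    paste(c(rownames(m)[i], vals), collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(NULL)
}

validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression data must be a numeric matrix")
  if (is.null(rownames(m))) stop("expression matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (nrow(m) < 2L) stop("need at least 2 genes")
  if (ncol(m) < 2L) stop("need at least 2 time points")
  obs <- m[!is.na(m)]
  if (any(obs < 0)) stop("expression values must be nonnegative")
  invisible(m)
}

#' Impute missing values by k-nearest-neighbour averaging
#'
#' Missing cells are filled gene-wise: the neighbours of a gene are the other
#' genes ranked by Euclidean distance computed over the time points observed
#' in both series, restricted to genes observed at the target time point.  The
#' imputed value is the mean of the k nearest eligible neighbours' values at
#' that time point (all eligible neighbours if fewer than k).  Distances are
#' computed on the original observed data only, so observed entries are never
#' changed and the result does not depend on the order in which cells are
#' filled.  Distance ties are broken by input row order.
#'
#' @param m Expression matrix (possibly with `NA` entries).
#' @param k Number of neighbours, a positive integer `< nrow(m)`.
#' @return The matrix with all `NA` entries replaced.
#' @export
impute_knn <- function(m, k = 5L) {
  validate_expression(m)
  k <- as.integer(k)
  if (k < 1L || k >= nrow(m)) stop("k must be in [1, n_genes - 1]")
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0L)) {
    stop("gene with no observed values: ",
         rownames(m)[which(rowSums(!is.na(m)) == 0L)[1L]])
  }
  obs <- !is.na(m)
  out <- m
  for (g in seq_len(nrow(m))) {
    for (t in which(!obs[g, ])) {
      cand <- setdiff(which(obs[, t]), g)
      d <- vapply(cand, function(h) {
        shared <- obs[g, ] & obs[h, ]
        if (!any(shared)) return(NA_real_)
        sqrt(sum((m[g, shared] - m[h, shared])^2))
      }, numeric(1L))
      cand <- cand[!is.na(d)]
      d <- d[!is.na(d)]
      if (length(cand) == 0L) {
        stop("no eligible neighbour to impute gene ", rownames(m)[g],
             " at time point ", t)
      }
      pick <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
      out[g, t] <- mean(m[pick, t])
    }
  }
  out
}

#' Min-max normalize each gene to [0, 1]
#'
#' Per gene g: `(g - min(g)) / (max(g) - min(g))`, so every row attains 0 at
#' its minimum and 1 at its maximum.  The result is invariant to positive
#' affine transforms of a gene's series.
#'
#' @param m Complete (no `NA`) expression matrix.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
normalize_minmax <- function(m) {
  validate_expression(m)
  if (anyNA(m)) stop("missing values present; impute before normalizing")
  rng <- apply(m, 1L, range)
  flat <- rng[2L, ] - rng[1L, ]
  if (any(flat == 0)) {
    stop("constant gene cannot be normalized: ",
         rownames(m)[which(flat == 0)[1L]])
  }
  (m - rng[1L, ]) / flat
}

# ---- signed directed networks ------------------------------------------------

#' Construct a signed directed network
#'
#' @param source,target Character vectors of gene ids (equal length).
#' @param sign Character vector, each `"activator"` or `"repressor"`.
#' @param score Positive integer support scores (default 1).
#' @return A `data.frame` with columns `source`, `target`, `sign`, `score`,
#'   lexicographically ordered; no self-edges, at most one row per
#'   (source, target, sign).
#' @export
signed_network <- function(source = character(), target = character(),
                           sign = character(), score = rep(1L, length(source))) {
  net <- data.frame(source = as.character(source), target = as.character(target),
                    sign = as.character(sign), score = as.integer(score),
                    stringsAsFactors = FALSE)
  validate_network(net)
  net <- net[order(net$source, net$target, net$sign), , drop = FALSE]
  rownames(net) <- NULL
  net
}

validate_network <- function(net) {
  stopifnot(is.data.frame(net),
            all(c("source", "target", "sign", "score") %in% names(net)))
  if (any(net$source == net$target)) stop("self-edges are not allowed")
  if (!all(net$sign %in% c("activator", "repressor"))) {
    stop("sign must be 'activator' or 'repressor'")
  }
  if (anyDuplicated(net[c("source", "target", "sign")])) {
    stop("duplicate (source, target, sign) edge")
  }
  if (any(net$score < 1L)) stop("edge scores must be positive integers")
  invisible(net)
}

sign_to_relation <- c(activator = "activates", repressor = "represses")
relation_to_sign <- c(activates = "activator", represses = "repressor")

#' Write a signed network to SIF or TSV
#'
#' SIF lines are `SOURCE<tab>activates|represses<tab>TARGET`; the TSV format
#' adds a header and the net-support `score` column.  Edges are written in
#' lexicographic (source, target, sign) order so output bytes are
#' deterministic.
#'
#' @param net Network as returned by [signed_network()].
#' @param path Output path.
#' @param format `"sif"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  validate_network(net)
  net <- net[order(net$source, net$target, net$sign), , drop = FALSE]
  lines <- if (format == "sif") {
    sprintf("%s\t%s\t%s", net$source, sign_to_relation[net$sign], net$target)
  } else {
    c("source\ttarget\tsign\tscore",
      sprintf("%s\t%s\t%s\t%d", net$source, net$target, net$sign, net$score))
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write network to ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

#' Read a signed network from SIF or TSV
#'
#' @param path Input path.
#' @param format `"sif"` or `"tsv"`; default guesses from the file extension
#'   (`.sif` vs anything else).
#' @return A [signed_network()] data frame (SIF edges get score 1).
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  format <- match.arg(format, c("sif", "tsv"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "tsv" && length(lines) > 0L) lines <- lines[-1L]  # header
  if (length(lines) == 0L) return(signed_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (format == "sif") 3L else 4L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    lineno <- i + (format == "tsv")
    if (length(f) != need) {
      stop("malformed network line ", lineno, ": expected ", need, " fields")
    }
    rel <- f[[2L + (format == "tsv")]]
    ok <- if (format == "sif") rel %in% names(relation_to_sign)
          else rel %in% c("activator", "repressor")
    if (!ok) stop("malformed network line ", lineno, ": unknown relation '", rel, "'")
  }
  mat <- do.call(rbind, fields)
  if (format == "sif") {
    signed_network(mat[, 1L], mat[, 3L], unname(relation_to_sign[mat[, 2L]]))
  } else {
    signed_network(mat[, 1L], mat[, 2L], mat[, 3L], as.integer(mat[, 4L]))
  }
}
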
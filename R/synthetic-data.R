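# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration of the synthetic benchmark generator
#'
#' Defaults emulate the short yeast cell-cycle microarray series the method
#' targets: 12 genes observed at 24 time points, a sparse ground-truth
#' network, sigmoidal interactions strong enough to dominate the noise, and
#' optionally missing cells.
#'
#' @param n_genes Number of genes (default 12).
#' @param n_timepoints Number of time points (default 24).
#' @param edge_count Number of ground-truth edges (default 15).
#' @param repressor_fraction Probability an edge is a repressor (default 0.3).
#' @param interaction_strength Sigmoid input gain per regulator (default 3).
#' @param noise_sd Gaussian noise SD on the latent \[0, 1\] scale
#'   (default 0.05).
#' @param missing_fraction Fraction of cells to blank out (default 0).
#' @param seed Integer seed driving all randomness.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 12L, n_timepoints = 24L,
                              edge_count = 15L, repressor_fraction = 0.3,
                              interaction_strength = 3, noise_sd = 0.05,
                              missing_fraction = 0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_timepoints = as.integer(n_timepoints),
              edge_count = as.integer(edge_count),
              repressor_fraction = repressor_fraction,
              interaction_strength = interaction_strength,
              noise_sd = noise_sd,
              missing_fraction = missing_fraction,
              seed = as.integer(seed))
  if (cfg$n_genes < 2L) stop("need at least 2 genes")
  if (cfg$n_timepoints < 2L) stop("need at least 2 time points")
  if (cfg$edge_count < 0L || cfg$edge_count > cfg$n_genes * (cfg$n_genes - 1L)) {
    stop("edge_count must be in [0, n_genes * (n_genes - 1)]")
  }
  if (cfg$repressor_fraction < 0 || cfg$repressor_fraction > 1) {
    stop("repressor_fraction must be in [0, 1]")
  }
  if (cfg$interaction_strength <= 0) stop("interaction_strength must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%02d", seq_len(n))

#' Generate a random ground-truth signed network
#'
#' Draws `edge_count` distinct directed non-self edges uniformly at random
#' (seeded), each marked repressor with probability `repressor_fraction`.
#'
#' @param cfg [simulation_config()].
#' @return A [signed_network()] (scores 1).
#' @export
generate_grn <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_ids(cfg$n_genes)
  if (cfg$edge_count == 0L) return(signed_network())
  with_seed(cfg$seed, {
    pairs <- expand.grid(source = seq_len(cfg$n_genes),
                         target = seq_len(cfg$n_genes))
    pairs <- pairs[pairs$source != pairs$target, ]
    pick <- pairs[sample(nrow(pairs), cfg$edge_count), ]
    sign <- ifelse(stats::runif(cfg$edge_count) < cfg$repressor_fraction,
                   "repressor", "activator")
    signed_network(genes[pick$source], genes[pick$target], sign)
  })
}

#' Simulate a gene-by-time-point expression matrix from a network
#'
#' Discrete-time sigmoidal dynamics: regulated genes follow
#' `x_g(t+1) = clamp01( logistic( strength * sum_r sign_r * x_r(t) ) + noise )`
#' with `sign_r = +1` for activators and `-1` for repressors of g, starting
#' from `x_g(0) ~ Uniform(0.2, 0.8)`.  Unregulated genes follow a seeded
#' smooth sinusoidal baseline (random phase and period) plus noise, mimicking
#' cycling transcripts.  The latent \[0, 1\] trajectories are finally mapped
#' to a positive microarray-like range (10-100).  Deliberately NOT a
#' fuzzy-rule process, so recovery tests do not feed the inference method its
#' own model class.
#'
#' @param net Ground-truth [signed_network()] over the configured genes.
#' @param cfg [simulation_config()].
#' @return Expression matrix (genes x time points, no missing values).
#' @export
simulate_expression <- function(net, cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_ids(cfg$n_genes)
  if (!all(c(net$source, net$target) %in% genes)) {
    stop("network genes outside the configured universe")
  }
  regulators <- lapply(genes, function(g) {
    rows <- net$target == g
    list(src = match(net$source[rows], genes),
         sgn = ifelse(net$sign[rows] == "activator", 1, -1))
  })
  clamp01 <- function(v) pmin(1, pmax(0, v))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_genes
    T_ <- cfg$n_timepoints
    x <- matrix(0, n, T_, dimnames = list(genes, paste0("T", seq_len(T_))))
    x[, 1L] <- stats::runif(n, 0.2, 0.8)
    period <- stats::runif(n, 8, 14)
    phase <- stats::runif(n, 0, 2 * pi)
    for (t in seq_len(T_ - 1L)) {
      eps <- stats::rnorm(n, 0, cfg$noise_sd)
      for (g in seq_len(n)) {
        reg <- regulators[[g]]
        x[g, t + 1L] <- if (length(reg$src)) {
          drive <- cfg$interaction_strength * sum(reg$sgn * x[reg$src, t])
          clamp01(stats::plogis(drive) + eps[g])
        } else {
          clamp01(0.5 + 0.3 * sin(2 * pi * (t + 1) / period[g] + phase[g]) +
                    eps[g])
        }
      }
    }
    10 + 90 * x
  })
}

#' Blank out a fraction of cells at random
#'
#' Sets `floor(fraction * n_cells)` observed cells to `NA`, uniformly at
#' random under the given seed.  If a draw would leave some gene with no
#' observed value the mask is redrawn (up to 100 attempts).
#'
#' @param m Complete expression matrix.
#' @param fraction Fraction in \[0, 1).
#' @param seed Integer seed.
#' @return The matrix with missing entries injected.
#' @export
inject_missing <- function(m, fraction, seed = 1L) {
  validate_expression(m)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_missing <- floor(fraction * length(m))
  if (n_missing == 0L) return(m)
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      cells <- sample(length(m), n_missing)
      out <- m
      out[cells] <- NA_real_
      if (all(rowSums(!is.na(out)) >= 1L)) return(out)
    }
    stop("could not draw a missing-value mask leaving every gene observed")
  })
}
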
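test_that("connections follow the zero-source / nonzero-target rule", {
  es <- c(G1 = 0L, G2 = 1L, G3 = -1L)
  cs <- extract_connections(es)
  expect_identical(cs$activators,
                   matrix(c("G1", "G2"), 1, 2,
                          dimnames = list(NULL, c("source", "target"))))
  expect_identical(cs$repressors,
                   matrix(c("G1", "G3"), 1, 2,
                          dimnames = list(NULL, c("source", "target"))))

  none <- extract_connections(c(G1 = 0L, G2 = 0L, G3 = 0L))
  expect_identical(nrow(none$activators) + nrow(none$repressors), 0L)
  none2 <- extract_connections(c(G1 = 1L, G2 = -1L, G3 = 1L))
  expect_identical(nrow(none2$activators) + nrow(none2$repressors), 0L)
})

test_that("connection counts equal #zeros x #nonzeros for every ES vector", {
  # brute-force oracle: enumerate ordered pairs directly
  oracle <- function(es) {
    pairs <- list(activators = NULL, repressors = NULL)
    for (i in seq_along(es)) for (p in seq_along(es)) {
      if (i != p && es[i] == 0L && es[p] != 0L) {
        kind <- if (es[p] == 1L) "activators" else "repressors"
        pairs[[kind]] <- rbind(pairs[[kind]], c(names(es)[i], names(es)[p]))
      }
    }
    pairs
  }
  for (n in 2:5) {
    grid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n)))
    for (r in seq_len(nrow(grid))) {
      es <- grid[r, ]
      names(es) <- paste0("G", seq_len(n))
      cs <- extract_connections(es)
      n_pairs <- nrow(cs$activators) + nrow(cs$repressors)
      expect_identical(n_pairs, sum(es == 0L) * sum(es != 0L))
      orc <- oracle(es)
      expect_setequal(apply(rbind(cs$activators, cs$repressors), 1,
                            paste, collapse = ">"),
                      if (is.null(orc$activators) && is.null(orc$repressors))
                        character(0)
                      else apply(rbind(orc$activators, orc$repressors), 1,
                                 paste, collapse = ">"))
    }
  }
})

test_that("criterion matrices count rules supporting each ordered pair", {
  genes <- c("G1", "G2", "G3")
  cs <- extract_connections(c(G1 = 0L, G2 = 1L, G3 = 0L))
  crit <- accumulate_criteria(list(cs), genes)
  expect_identical(sum(crit$AC), 2L)        # G1->G2 and G3->G2
  expect_identical(crit$AC["G1", "G2"], 1L)
  expect_identical(crit$AC["G3", "G2"], 1L)
  expect_identical(sum(crit$RC), 0L)
  expect_identical(unname(diag(crit$AC)), rep(0L, 3))

  # additivity: k identical connection sets scale the counts by k
  crit5 <- accumulate_criteria(rep(list(cs), 5), genes)
  expect_identical(crit5$AC, crit$AC * 5L)

  # conservation: AC + RC totals equal total extracted pairs across rules
  set.seed(21)
  conns <- lapply(1:30, function(i) {
    es <- sample(c(-1L, 0L, 1L), 4, replace = TRUE)
    names(es) <- paste0("G", 1:4)
    extract_connections(es)
  })
  crit_all <- accumulate_criteria(conns, paste0("G", 1:4))
  total_pairs <- sum(vapply(conns, function(cs)
    nrow(cs$activators) + nrow(cs$repressors), integer(1)))
  expect_identical(sum(crit_all$AC) + sum(crit_all$RC), total_pairs)
})

test_that("net interaction is the antisymmetric pairwise subtraction", {
  C <- matrix(0L, 2, 2); C[1, 2] <- 3L; C[2, 1] <- 1L
  net <- net_interaction(C)
  expect_identical(net[1, 2], 2L)
  expect_identical(net[2, 1], -2L)

  S <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_true(all(net_interaction(S) == 0))

  set.seed(2)
  M <- matrix(sample(0:5, 25, replace = TRUE), 5, 5); diag(M) <- 0L
  expect_equal(net_interaction(M), -t(net_interaction(M)))
  bad <- M; diag(bad) <- 1L
  expect_error(net_interaction(bad), "zero diagonal")
})

test_that("finalization keeps strictly positive net support only", {
  genes <- c("A", "B", "C")
  z <- matrix(0L, 3, 3, dimnames = list(genes, genes))
  expect_identical(nrow(finalize_network(z, z)), 0L)

  ac <- z; ac["A", "B"] <- 2L; ac["B", "A"] <- -2L
  net <- finalize_network(ac, z)
  expect_identical(nrow(net), 1L)
  expect_identical(net$source, "A")
  expect_identical(net$target, "B")
  expect_identical(net$sign, "activator")
  expect_identical(net$score, 2L)

  # an exact tie (net count 0 both ways) emits no edge
  expect_identical(nrow(finalize_network(z, z, min_score = 1L)), 0L)
  # min_score raises the bar
  expect_identical(nrow(finalize_network(ac, z, min_score = 3L)), 0L)

  # antisymmetry: both directions with the same sign can never co-occur
  set.seed(14)
  for (i in 1:10) {
    A <- matrix(sample(0:4, 16, replace = TRUE), 4, 4,
                dimnames = list(paste0("G", 1:4), paste0("G", 1:4)))
    R <- matrix(sample(0:4, 16, replace = TRUE), 4, 4,
                dimnames = dimnames(A))
    diag(A) <- diag(R) <- 0L
    net <- finalize_network(net_interaction(A), net_interaction(R))
    key_fwd <- paste(net$source, net$target, net$sign)
    key_rev <- paste(net$target, net$source, net$sign)
    expect_false(any(key_fwd %in% key_rev))
  }
})

test_that("dominant-sign mode keeps one sign per ordered pair", {
  genes <- c("A", "B")
  netAC <- matrix(c(0L, -2L, 2L, 0L), 2, 2, dimnames = list(genes, genes))
  netRC <- matrix(c(0L, -1L, 1L, 0L), 2, 2, dimnames = list(genes, genes))
  both <- finalize_network(netAC, netRC)
  expect_identical(nrow(both), 2L)   # A->B carries both signs by default
  expect_setequal(both$sign, c("activator", "repressor"))
  dom <- finalize_network(netAC, netRC, dominant_sign = TRUE)
  expect_identical(nrow(dom), 1L)
  expect_identical(dom$sign, "activator")
  expect_identical(dom$score, 2L)
})
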
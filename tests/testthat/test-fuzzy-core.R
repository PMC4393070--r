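test_that("Gaussian membership matches its closed form and is symmetric", {
  expect_equal(gaussian_membership(0.2, 0.2, 0.25), 1.0)
  expect_equal(gaussian_membership(0.2, 0.2, 7), 1.0)
  # (0.5 - 0.2)^2 / 0.25 = 0.36
  expect_equal(gaussian_membership(0.5, 0.2, 0.25), exp(-0.36))
  expect_equal(gaussian_membership(0.5, 0.2, 0.25), 0.697676, tolerance = 1e-6)

  set.seed(1)
  d <- runif(50, 0, 0.5)
  expect_equal(gaussian_membership(0.5 + d, 0.5, 0.25),
               gaussian_membership(0.5 - d, 0.5, 0.25))

  expect_error(gaussian_membership(0.5, 0.2, 0), "positive")
  expect_error(gaussian_membership(0.5, 0.2, -1), "positive")
})

test_that("fuzzification produces a genes x time x labels tensor in (0, 1]", {
  nm <- tiny_normalized()
  mt <- fuzzify(nm)
  expect_identical(dim(mt), c(3L, 4L, 3L))
  expect_identical(dimnames(mt)[[3]], c("Low", "Medium", "High"))
  expect_true(all(mt > 0 & mt <= 1))
  # values pinned at centers reach degree 1 for the matching label
  expect_equal(mt["A", 1, "Low"], 1)
  expect_equal(mt["A", 2, "Medium"], 1)
  expect_equal(mt["A", 3, "High"], 1)
  # 0.35 is equidistant from the Low and Medium centers
  mt2 <- fuzzify(matrix(0.35, 2, 2, dimnames = list(c("A", "B"), NULL)))
  expect_equal(mt2[1, 1, "Low"], mt2[1, 1, "Medium"], tolerance = 1e-12)
})

test_that("dominant label takes the argmax with low-center tie-break", {
  expect_identical(dominant_label(c(0.9, 0.4, 0.1)), 1L)
  expect_identical(dominant_label(c(0.7, 0.7, 0.1)), 1L)
  expect_identical(dominant_label(c(0.1, 0.2, 0.9)), 3L)
  # 0.65 ties Medium and High; the lower-center label wins
  p <- mf_params()
  deg <- gaussian_membership(0.65, p$centers, p$variance)
  expect_identical(dominant_label(deg), 2L)
})

test_that("rule bases merge duplicate antecedents with majority consequents", {
  nm <- tiny_normalized()
  # dominant labels per time point: A = L,M,H,L; B = L,L,M,L; C = H,M,L,H
  rb <- build_rulebase(fuzzify(nm), target_index = 3L)
  # antecedents over (A, B): (L,L), (M,L), (H,M), (L,L) -> 3 rules
  expect_identical(nrow(rb$antecedents), 3L)
  expect_identical(rb$support, c(2L, 1L, 1L))
  expect_identical(rb$consequents[1], 3L)  # C is High both times
  expect_identical(rb$target_gene, "C")
  expect_identical(rb$input_genes, c("A", "B"))

  # single time point: exactly one rule with support 1
  one <- fuzzify(matrix(c(0.1, 0.9), 2, 1, dimnames = list(c("A", "B"), NULL)))
  rb1 <- build_rulebase(one, 1L)
  expect_identical(nrow(rb1$antecedents), 1L)
  expect_identical(rb1$support, 1L)

  # consequent ties resolve to the first-seen label
  nm2 <- rbind(A = c(0.2, 0.21), B = c(0.2, 0.19), C = c(0.2, 0.8))
  rb2 <- build_rulebase(fuzzify(nm2), target_index = 3L)
  expect_identical(nrow(rb2$antecedents), 1L)
  expect_identical(rb2$consequents, 1L)   # Low seen first
  expect_identical(rb2$support, 2L)
})

test_that("rule count never exceeds the sample count and antecedents are unique", {
  for (seed in 1:5) {
    nm <- normalize_minmax(random_expression(n_genes = 5, n_time = 12,
                                             seed = seed))
    rb <- build_rulebase(fuzzify(nm), 2L)
    expect_lte(nrow(rb$antecedents), ncol(nm))
    keys <- apply(rb$antecedents, 1, paste, collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("firing strength is the product T-norm and matches the matrix form", {
  p <- mf_params()
  expect_equal(firing_strength(c(1L, 2L, 3L), c(0.2, 0.5, 0.8), p), 1.0)
  expect_equal(firing_strength(c(1L, 1L), c(0.5, 0.5), p), exp(-0.72))
  expect_error(firing_strength(c(1L, 2L), 0.5, p), "length")

  # oracle: quadratic form exp(-(x - c)' diag(1/sigma^2) (x - c))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    labs <- sample(3, n, replace = TRUE)
    x <- runif(n)
    q <- sum((x - p$centers[labs])^2 / p$variance)
    expect_equal(firing_strength(labs, x, p), exp(-q))
  }

  # strictly decreases as any coordinate moves away from its label center
  base <- firing_strength(c(2L, 2L), c(0.5, 0.5), p)
  expect_lt(firing_strength(c(2L, 2L), c(0.5, 0.6), p), base)
})

test_that("normalized firing powers form a simplex", {
  expect_equal(normalize_firing(5), 1.0)
  expect_equal(normalize_firing(rep(0.3, 4)), rep(0.25, 4))
  expect_equal(normalize_firing(c(0.2, 0.2, 0.6)), c(0.2, 0.2, 0.6))
  set.seed(3)
  for (i in 1:50) {
    s <- runif(sample(1:10, 1), min = 1e-6)
    expect_equal(sum(normalize_firing(s)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_firing(numeric(0)), "at least one")
  expect_error(normalize_firing(c(0, 0)), "underflow")
})

test_that("defuzzification is the weighted sum of firing powers", {
  expect_equal(defuzzify(c(0.25, 0.75), c(0.4, 0.8)), 0.7)
  expect_equal(defuzzify(c(0.1, 0.3, 0.6), rep(0.42, 3)), 0.42)
  expect_equal(defuzzify(1, 0.9), 0.9)
  expect_error(defuzzify(c(0.5, 0.5), 1), "length")
})

test_that("membership parameters are validated", {
  expect_error(mf_params(centers = c(0.5, 0.2)), "increasing")
  expect_error(mf_params(centers = c(0.2, 1.5)), "\\[0, 1\\]")
  expect_error(mf_params(variance = 0), "positive")
  expect_error(mf_params(labels = c("a", "b")), "one label per center")
})
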
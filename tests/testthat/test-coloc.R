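test_that("binarize splits a two-level image exactly and rejects constants", {
  img <- matrix(c(10, 10, 200, 200, 10, 200), 2)
  m <- binarize(img)
  expect_identical(unclass(m)[, ], img == 200)
  expect_true(attr(m, "threshold") > 10 && attr(m, "threshold") < 200)
  expect_error(binarize(matrix(5, 4, 4)), "non-constant")
  expect_error(binarize(matrix(-1, 2, 2)), "non-negative")
})

test_that("fixed and quantile thresholding behave as documented", {
  img <- matrix(seq(0, 99), 10)
  expect_equal(sum(binarize(img, "fixed", threshold = 49.5)), 50)
  expect_equal(sum(binarize(img, "quantile", quantile = 0.9)), 10)
  expect_error(binarize(img, "fixed"), "threshold")
  expect_error(binarize(img, "quantile", quantile = 1.2), "quantile")
})

test_that("quantile masks are invariant to monotone intensity rescaling", {
  set.seed(1)
  img <- matrix(rgamma(400, 2, 1), 20)
  m1 <- binarize(img, "quantile", quantile = 0.7)
  for (f in list(function(x) 3 * x + 2, sqrt, function(x) x^3))
    expect_identical(unclass(binarize(f(img), "quantile", quantile = 0.7))[, ],
                     unclass(m1)[, ])
})

test_that("colocalized fraction identities: subset, disjoint, counted overlap", {
  fx <- make_coloc_fixture(0.3, n_a = 10000L)
  expect_equal(coloc_fraction(fx$mask_a, fx$mask_b)$fraction, 0.3)

  sub <- make_coloc_fixture(1, n_a = 2000L)
  expect_equal(coloc_fraction(sub$mask_a, sub$mask_b)$fraction, 1)

  dis <- make_coloc_fixture(0, n_a = 2000L)
  expect_equal(coloc_fraction(dis$mask_a, dis$mask_b)$fraction, 0)

  expect_error(coloc_fraction(matrix(FALSE, 4, 4), matrix(TRUE, 4, 4)),
               "undefined fraction")
  expect_error(coloc_fraction(matrix(TRUE, 4, 4), matrix(TRUE, 2, 2)),
               "dimensions")
})

test_that("fraction(A,B) + fraction(A,!B) = 1 for non-empty A", {
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(runif(900) < 0.3, 30)
    b <- matrix(runif(900) < 0.5, 30)
    if (!any(a)) next
    expect_equal(coloc_fraction(a, b)$fraction + coloc_fraction(a, !b)$fraction, 1)
  }
})

test_that("permuting B outside A's bounding region leaves the fraction unchanged", {
  fx <- make_coloc_fixture(0.4, n_a = 5000L)
  base <- coloc_fraction(fx$mask_a, fx$mask_b)$fraction
  b2 <- fx$mask_b
  cols <- which(colSums(fx$mask_a) > 0)
  outside_cols <- setdiff(seq_len(ncol(b2)), cols)
  set.seed(3)
  b2[, outside_cols] <- b2[, sample(outside_cols)]
  expect_equal(coloc_fraction(fx$mask_a, b2)$fraction, base)
})

test_that("the binarize-then-overlap pipeline recovers fixture truth at default noise", {
  for (f in c(0, 0.3, 1)) {
    fx <- make_coloc_fixture(f, n_a = 10000L, seed = 17)
    ma <- binarize(fx$channel_a)
    # thresholded mask recovers at least 98% of the true positive set
    expect_gte(sum(ma & fx$mask_a) / sum(fx$mask_a), 0.98)
    r <- nuclear_fraction(fx$channel_a, fx$channel_b)
    expect_lt(abs(r$fraction - f), 0.02)
    expect_false(is.null(r$threshold_a))
  }
})
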
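test_that("pearsonR matches hand-computed and limiting cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, 2 * x + 1), 1)
  expect_equal(pearsonR(x, -x), -1)
  expect_equal(pearsonR(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearsonR(1:4, 1:3), "length")
  expect_error(pearsonR(c(1, 2), c(3, 4)), "3 observations")
  expect_error(pearsonR(c(1, 1, 1), 1:3), "constant")
})

test_that("pearsonR is affine-invariant and sign-flips under negation", {
  set.seed(10)
  x <- rnorm(20)
  y <- rnorm(20)
  r <- pearsonR(x, y)
  expect_equal(pearsonR(3 * x + 7, y), r)
  expect_equal(pearsonR(x, 0.1 * y - 2), r)
  expect_equal(pearsonR(-x, y), -r)
})

test_that("regressionSe equals sqrt(SSE/(n-2)) from a least-squares fit", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 4)
  # closed form: slope 1.5, intercept -2/3, SSE = 1/6
  expect_equal(regressionSe(x, y), sqrt((1 / 6) / 1))
  expect_equal(regressionSe(1:5, 2 * (1:5) + 3), 0)
  # constant response: the fitted line is the mean, se from residuals
  yc <- rep(2, 5)
  expect_equal(regressionSe(1:5, yc), 0)
  set.seed(3)
  x <- rnorm(15)
  y <- 2 * x + rnorm(15)
  fit <- lm(y ~ x)
  expect_equal(regressionSe(x, y), summary(fit)$sigma)
  expect_error(regressionSe(rep(1, 5), rnorm(5)), "constant")
})

test_that("qsprTable reports one r and se per index column", {
  set.seed(8)
  idx <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  prop <- idx[, 1] + rnorm(10, sd = 0.2)
  tab <- qsprTable(prop, idx)
  expect_identical(tab$index, colnames(idx))
  expect_equal(tab$r[1], pearsonR(idx[, 1], prop))
  expect_equal(tab$se[2], regressionSe(idx[, 2], prop))
})

test_that("ratio weights normalize, preserve order, and match the case study", {
  wbp <- ratioWeights(correlationVector("bp"))
  expect_equal(sum(wbp), 1)
  expect_equal(unname(wbp["F"]), 0.693 / 5.125)
  # matches the published weight to its 9 printed decimals
  expect_lt(abs(unname(wbp["F"]) - 0.135219512), 5e-10)
  wev <- ratioWeights(correlationVector("ev"))
  expect_equal(unname(wev["F"]), 0.787 / 6.437)
  expect_lt(abs(unname(wev["F"]) - 0.122261923), 5e-10)
  expect_identical(order(wbp), order(correlationVector("bp")))

  expect_equal(unname(ratioWeights(c(a = 2, b = 2, c = 2, d = 2))),
               rep(0.25, 4))
  expect_error(ratioWeights(c(a = 0.5, b = -0.1)), "positive")
  expect_error(ratioWeights(c(0.5, 0.5)), "names")
})

test_that("classification splits the case-study criteria as published", {
  for (p in c("bp", "ev")) {
    w <- ratioWeights(correlationVector(p))
    orient <- classifyCriteria(w, threshold = 0.11)
    expect_setequal(names(orient)[orient == "beneficial"],
                    c("RA", "ABC", "F", "GA", "HM"))
    expect_setequal(names(orient)[orient == "non_beneficial"],
                    c("M1", "M2", "SCI", "H"))
  }
  w9 <- setNames(rep(1 / 9, 9), letters[1:9])
  expect_true(all(classifyCriteria(w9, 0.10) == "beneficial"))
})

test_that("classification is monotone in the threshold", {
  w <- ratioWeights(correlationVector("bp"))
  prev <- classifyCriteria(w, 0.02) == "beneficial"
  for (th in seq(0.04, 0.2, by = 0.02)) {
    cur <- classifyCriteria(w, th) == "beneficial"
    expect_true(all(prev | !cur))  # raising never converts non-ben -> ben
    prev <- cur
  }
})

test_that("criterionSet validates weights and orientations", {
  w <- c(a = 0.6, b = 0.4)
  cs <- criterionSet(w, c(a = "beneficial", b = "non_beneficial"))
  expect_identical(criteria(cs), c("a", "b"))
  expect_equal(criterionWeights(cs), w)
  cs2 <- criterionSet(w, "beneficial")
  expect_true(all(criterionOrientations(cs2) == "beneficial"))
  expect_error(criterionSet(c(a = 0.6, b = 0.6), "beneficial"), "sum")
  expect_error(criterionSet(w, c(a = "beneficial", b = "sideways")),
               "orientation")
})
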
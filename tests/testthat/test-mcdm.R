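mk_dm <- function(values, alts = NULL, crits = NULL) {
  if (is.null(alts)) alts <- paste0("alt", seq_len(nrow(values)))
  if (is.null(crits)) crits <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(alts, crits)
  decisionMatrix(values)
}

uniform_cs <- function(crits, orientation = "beneficial") {
  criterionSet(setNames(rep(1 / length(crits), length(crits)), crits),
               orientation)
}

test_that("ideal points follow criterion orientation", {
  dm <- mk_dm(matrix(c(1, 5, 3), ncol = 1))
  ben <- uniform_cs("c1", "beneficial")
  nb <- uniform_cs("c1", "non_beneficial")
  expect_equal(idealPoints(dm, ben)$best, 5)
  expect_equal(idealPoints(dm, ben)$worst, 1)
  expect_equal(idealPoints(dm, nb)$best, 1)
  expect_equal(idealPoints(dm, nb)$worst, 5)
})

test_that("case-study ideal point for ABC spans Ciclesonide to Epinephrine", {
  dm <- lungDecisionMatrix()
  ip <- idealPoints(dm, caseStudyCriteria("bp"))
  expect_equal(ip["ABC", "best"], 33.0791)
  expect_equal(ip["ABC", "worst"], 9.439677)
})

test_that("constant criteria are dropped with a warning or raise on request", {
  vals <- cbind(c(1, 2, 3), c(7, 7, 7))
  dm <- mk_dm(vals)
  cs <- uniform_cs(c("c1", "c2"))
  expect_warning(ip <- idealPoints(dm, cs), "constant")
  expect_identical(rownames(ip), "c1")
  expect_error(idealPoints(dm, cs, onConstant = "error"), "constant")
  expect_warning(res <- vikor(dm, cs), "constant")
  expect_identical(criteria(res@criteria), "c1")
})

test_that("two-alternative single-criterion VIKOR hits the endpoints", {
  dm <- mk_dm(matrix(c(1, 0), ncol = 1))
  cs <- uniform_cs("c1")
  res <- vikor(dm, cs)
  expect_equal(unname(res@S), c(0, 1))
  expect_equal(unname(res@R), c(0, 1))
  expect_equal(unname(res@Q), c(0, 1))
})

test_that("degenerate spread is an explicit error", {
  # both alternatives equidistant: S and R spreads collapse
  dm <- mk_dm(rbind(c(1, 0), c(0, 1)))
  cs <- uniform_cs(c("c1", "c2"))
  expect_error(vikor(dm, cs), "degenerate")
})

test_that("VIKOR agrees with a brute-force oracle on random matrices", {
  set.seed(17)
  for (i in 1:25) {
    vals <- matrix(runif(12, 1, 10), 4, 3)
    dm <- mk_dm(vals)
    w <- runif(3)
    w <- w / sum(w)
    ben <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    cs <- criterionSet(setNames(w, c("c1", "c2", "c3")),
                       setNames(ifelse(ben, "beneficial", "non_beneficial"),
                                c("c1", "c2", "c3")))
    v <- runif(1)
    got <- vikor(dm, cs, v = v)
    want <- brute_vikor(vals, w, ben, v)
    expect_equal(unname(got@S), want$S, tolerance = 1e-12)
    expect_equal(unname(got@R), want$R, tolerance = 1e-12)
    expect_equal(unname(got@Q), want$Q, tolerance = 1e-12)
  }
})

test_that("Q stays in [0,1]; the all-worst alternative has Q = 1; R is bounded by the largest weight", {
  set.seed(23)
  for (i in 1:15) {
    vals <- matrix(runif(24, 1, 10), 6, 4)
    # force one alternative to dominate and one to be dominated
    vals[1, ] <- apply(vals, 2, max) + 1
    vals[2, ] <- apply(vals, 2, min) - 0.5
    dm <- mk_dm(vals)
    w <- runif(4); w <- w / sum(w)
    cs <- criterionSet(setNames(w, paste0("c", 1:4)), "beneficial")
    res <- vikor(dm, cs)
    expect_true(all(res@Q >= 0 & res@Q <= 1))
    expect_equal(unname(res@Q[2]), 1)    # attains S- and R- simultaneously
    expect_equal(unname(res@S[1]), 0)
    expect_true(all(res@R <= max(w) + 1e-12))
    expect_true(all(res@S >= 0 & res@S <= 1 + 1e-12))
  }
})

test_that("v = 1 reduces Q-ranking to S-ranking and v = 0 to R-ranking", {
  set.seed(29)
  vals <- matrix(runif(45, 1, 10), 9, 5)
  dm <- mk_dm(vals)
  w <- runif(5); w <- w / sum(w)
  cs <- criterionSet(setNames(w, paste0("c", 1:5)),
                     setNames(sample(c("beneficial", "non_beneficial"), 5,
                                     replace = TRUE), paste0("c", 1:5)))
  resS <- vikor(dm, cs, v = 1)
  expect_identical(resS@ranks$byQ, resS@ranks$byS)
  resR <- vikor(dm, cs, v = 0)
  expect_identical(resR@ranks$byQ, resR@ranks$byR)
})

test_that("per-criterion positive affine transforms leave VIKOR unchanged", {
  set.seed(37)
  vals <- matrix(runif(40, 1, 10), 8, 5)
  dm <- mk_dm(vals)
  w <- runif(5); w <- w / sum(w)
  orient <- setNames(sample(c("beneficial", "non_beneficial"), 5,
                            replace = TRUE), paste0("c", 1:5))
  cs <- criterionSet(setNames(w, paste0("c", 1:5)), orient)
  base <- vikor(dm, cs)
  vals2 <- vals
  for (j in 1:5) vals2[, j] <- runif(1, 0.1, 5) * vals2[, j] + runif(1, -3, 3)
  res2 <- vikor(mk_dm(vals2), cs)
  expect_equal(res2@S, base@S)
  expect_equal(res2@R, base@R)
  expect_equal(res2@Q, base@Q)
})

test_that("rankScores uses competition ranking in both directions", {
  expect_identical(rankScores(c(0.3, 0.1, 0.2)), c(3L, 1L, 2L))
  expect_identical(rankScores(c(5, 5, 1)), c(2L, 2L, 1L))
  expect_identical(rankScores(c(5, 5, 1), "desc"), c(1L, 1L, 3L))
})

test_that("decision matrices reject missing cells and tiny shapes", {
  expect_error(mk_dm(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
  expect_error(mk_dm(matrix(1:2, 1, 2)), "two alternatives")
  m <- matrix(1:4, 2, 2)
  dimnames(m) <- list(c("a", "a"), c("x", "y"))
  expect_error(decisionMatrix(m), "unique")
})
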
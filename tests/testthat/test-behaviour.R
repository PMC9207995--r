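# Oracle for residual correlations computed from the correlation matrix
# alone (Schur-complement linear algebra), independent of the data-level
# implementation: for target t with regressor set S,
#   resid = t - R[t,S] R[S,S]^-1 S  (standardized variables), from which all
# correlations with original columns follow.
resid_corr_oracle <- function(R, target, regressors, other) {
  if (!length(regressors)) {
    return(R[target, other])
  }
  b <- solve(R[regressors, regressors, drop = FALSE],
             R[regressors, target])
  var_res <- R[target, target] - sum(R[target, regressors] * b)
  cov_other <- R[target, other] - sum(R[other, regressors] * b)
  cov_other / sqrt(var_res * R[other, other])
}

test_that("full residualization matches the closed form and removes shared variance", {
  # two traits, r = 0.6: corr(resid_A, A) = sqrt(1 - r^2) = 0.8
  d <- exact_corr_data(60, matrix(c(1, .6, .6, 1), 2, 2), seed = 2,
                       names = c("A", "B"))
  bt <- residualize_full(behaviour_table(d))
  ct <- correlation_table(bt)
  expect_equal(ct["A_resid", "A"], 0.8, tolerance = 1e-10)
  expect_lt(abs(ct["A_resid", "B"]), 1e-8)

  # three-trait printed matrix: residuals orthogonal to the other originals
  d3 <- exact_corr_data(172, trait_corr3(), seed = 3)
  bt3 <- residualize_full(behaviour_table(d3))
  ct3 <- correlation_table(bt3)
  expect_lt(abs(ct3["Social_resid", "Communication"]), 1e-8)
  expect_lt(abs(ct3["Social_resid", "RRBI"]), 1e-8)
  expect_lt(abs(ct3["Communication_resid", "Social"]), 1e-8)

  # uncorrelated traits: residuals are the centred originals
  du <- exact_corr_data(40, diag(2), seed = 4, names = c("A", "B"))
  btu <- residualize_full(behaviour_table(du))
  expect_equal(correlation_table(btu)["A_resid", "A"], 1, tolerance = 1e-10)
})

test_that("sequential residualization reproduces the printed residual pattern", {
  d <- exact_corr_data(172, trait_corr3(), seed = 7)
  bt <- residualize_sequential(behaviour_table(d),
                               order = c("RRBI", "Communication", "Social"))
  ct <- correlation_table(bt)
  # printed rows 4-6 of the domain-score table, tolerance 0.01 (inputs are
  # rounded to 2 dp; Social residual recomputes to ~0.735 vs printed 0.73)
  expect_equal(ct["Communication_resid", "Communication"], 0.93, tolerance = 0.01)
  expect_equal(ct["Communication_resid", "Social"], 0.56, tolerance = 0.01)
  expect_equal(ct["RRBI_resid", "RRBI"], 1.00, tolerance = 1e-10)
  expect_equal(ct["RRBI_resid", "Social"], 0.38, tolerance = 0.01)
  expect_equal(ct["Social_resid", "Social"], 0.73, tolerance = 0.01)
  expect_lt(abs(ct["Social_resid", "Communication"]), 1e-8)
  expect_lt(abs(ct["Social_resid", "RRBI"]), 1e-8)
  # Gram-Schmidt property: residual columns mutually orthogonal
  resid_cols <- grep("_resid$", colnames(ct), value = TRUE)
  off <- ct[resid_cols, resid_cols]; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
})

test_that("single trait and error paths behave", {
  d <- data.frame(A = rnorm(10))
  bt <- residualize_sequential(behaviour_table(d), order = "A")
  expect_equal(bt$A_resid, d$A - mean(d$A))
  expect_error(residualize_sequential(behaviour_table(
    data.frame(A = rnorm(10), B = rnorm(10))), order = c("A", "A")),
    "permutation")
  expect_error(residualize_full(behaviour_table(data.frame(A = rnorm(10)))),
               ">= 2 traits")
  # collinear traits rejected with names
  x <- rnorm(20)
  expect_error(residualize_full(behaviour_table(
    data.frame(A = x, B = 2 * x, C = rnorm(20)))), "collinear")
})

test_that("residual correlations agree with the Schur-complement oracle", {
  set.seed(11)
  for (rep in 1:5) {
    R <- cov2cor(crossprod(matrix(rnorm(16), 4, 4)) + 4 * diag(4))
    dimnames(R) <- list(LETTERS[1:4], LETTERS[1:4])
    d <- exact_corr_data(100, R, seed = rep)
    ctf <- correlation_table(residualize_full(behaviour_table(d)))
    for (tr in LETTERS[1:4]) for (other in setdiff(LETTERS[1:4], tr)) {
      expect_equal(ctf[paste0(tr, "_resid"), other],
                   resid_corr_oracle(R, tr, setdiff(LETTERS[1:4], tr), other),
                   tolerance = 1e-8)
    }
    ord <- sample(LETTERS[1:4])
    cts <- correlation_table(residualize_sequential(behaviour_table(d), ord))
    for (k in 2:4) {
      tr <- ord[k]
      expect_equal(cts[paste0(tr, "_resid"), ord[1]],
                   resid_corr_oracle(R, tr, ord[seq_len(k - 1)], ord[1]),
                   tolerance = 1e-8)
    }
  }
})

test_that("variance never increases under residualization", {
  set.seed(12)
  d <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(d) <- c("A", "B", "C")
  d$B <- d$A * 0.5 + d$B
  bt <- residualize_full(behaviour_table(d))
  for (tr in c("A", "B", "C"))
    expect_lte(var(bt[[paste0(tr, "_resid")]]), var(d[[tr]]) + 1e-12)
})

test_that("missing scores use complete cases per regression", {
  d <- exact_corr_data(50, trait_corr3(), seed = 13)
  d$Social[c(3, 9)] <- NA
  bt <- residualize_full(behaviour_table(d))
  expect_true(all(is.na(bt$Social_resid[c(3, 9)])))
  expect_true(all(is.na(bt$Communication_resid[c(3, 9)])))  # Social is a regressor
  models <- attr(bt, "residual_models")
  expect_identical(models$Social$n_used, 48L)
})

test_that("correlation_table flags constant columns instead of zeroing them", {
  d <- data.frame(A = rnorm(10), B = rep(1, 10))
  expect_warning(ct <- correlation_table(d), "constant")
  expect_true(is.na(ct["A", "B"]))
  expect_identical(ct["A", "A"], 1)
  d2 <- data.frame(x = rnorm(10))
  d2$y <- -d2$x
  expect_equal(correlation_table(d2)["x", "y"], -1)
})

test_that("behaviour CSV round-trips", {
  d <- exact_corr_data(20, diag(2), seed = 14, names = c("A", "B"))
  d$A[5] <- NA
  bt <- behaviour_table(d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_behaviour(bt, path)
  back <- read_behaviour(path)
  expect_equal(as.data.frame(back), as.data.frame(bt), tolerance = 1e-12)
  expect_identical(subject_ids(back), subject_ids(bt))
})
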
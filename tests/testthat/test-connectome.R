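test_that("Pearson connectome basics", {
  set.seed(1)
  ts <- matrix(rnorm(200), 50, 4)
  ts[, 2] <- ts[, 1]                      # duplicated column
  colnames(ts) <- paste0("R", 1:4)
  r <- connectome_pearson(ts)
  expect_equal(r[1, 2], 1)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  ts[, 3] <- 5
  expect_error(connectome_pearson(ts), "R3")
})

test_that("partial correlation conditions out indirect paths", {
  # 3-ROI chain: corr(X,Z) = corr(X,Y) * corr(Y,Z) implies partial ~ 0
  # oracle: (r_xz - r_xy r_yz) / sqrt((1 - r_xy^2)(1 - r_yz^2)) = 0
  cv <- matrix(c(1, .6, .36, .6, 1, .6, .36, .6, 1), 3, 3)
  ts <- make_timeseries(1, 50000, cv, seed = 2)[[1]]
  pc <- connectome_partial(ts, shrinkage = "none")
  expect_lt(abs(pc[1, 3]), 0.03)
  expect_gt(pc[1, 2], 0.3)

  # 2 ROIs: partial equals Pearson exactly (no conditioning set)
  ts2 <- make_timeseries(1, 100, matrix(c(1, .5, .5, 1), 2, 2), seed = 3)[[1]]
  expect_equal(connectome_partial(ts2, shrinkage = "none"),
               connectome_pearson(ts2), tolerance = 1e-10)

  # identity covariance: off-diagonals near zero (shrinkage only helps)
  ts3 <- make_timeseries(1, 2000, diag(5), seed = 4)[[1]]
  pc3 <- connectome_partial(ts3)
  expect_lt(max(abs(pc3[upper.tri(pc3)])), 0.1)
})

test_that("tangent embedding is centred at the reference and invertible", {
  cv <- diag(4); cv[1, 2] <- cv[2, 1] <- 0.4
  ts <- make_timeseries(6, 300, cv, seed = 5)
  cs <- connectome_set(lapply(ts, cov), metric = "covariance")
  tg <- connectome_tangent(cs)
  ref <- attr(tg, "reference")

  # group of identical matrices: every tangent vector is zero
  same <- connectome_tangent(connectome_set(
    list(a = ref, b = ref, c = ref), metric = "covariance"))
  for (m in same$matrices) expect_lt(max(abs(m)), 1e-8)

  # round trip C_g^{1/2} expm(T) C_g^{1/2} recovers each input
  rh <- netbridge:::sym_sqrtm(ref)
  for (k in seq_along(ts)) {
    rec <- rh %*% netbridge:::sym_expm(tg$matrices[[k]]) %*% rh
    expect_lt(max(abs(rec - cov(ts[[k]]))), 1e-6)
  }

  # non-PD input rejected with the subject named
  bad <- cs
  bad$matrices[[2]] <- matrix(0, 4, 4)
  expect_error(connectome_tangent(bad), "positive definite")
})

test_that("edge vectorization is the row-major upper triangle and round-trips", {
  m <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3,
              dimnames = list(paste0("R", 1:3), paste0("R", 1:3)))
  cs <- connectome_set(list(s1 = m), metric = "pearson")
  et <- vectorize_edges(cs)
  expect_identical(colnames(et$edges), c("R1_R2", "R1_R3", "R2_R3"))
  expect_equal(as.vector(et$edges), c(.1, .2, .3))
  back <- devectorize_edges(et)
  expect_equal(back$matrices$s1, m)
  # edge-count arithmetic: 300 ROIs -> 44850 edges
  expect_identical(nrow(netbridge:::upper_pairs(300)), 44850L)
})

test_that("confound regression orthogonalizes, is idempotent, keeps signal", {
  # NB: seeds deliberately differ; make_confounds(seed) consumes the same
  # generator stream, and reusing it would make noise edges exact copies of
  # the volume confounds (perfect fit, degenerate residuals)
  set.seed(601)
  n <- 500
  cf <- make_confounds(n, site_levels = 4, seed = 6)
  trait <- rnorm(n)
  edges <- matrix(rnorm(n * 6), n, 6)
  edges[, 1] <- 2 * cf$age + rnorm(n)          # confound-driven edge
  edges[, 2] <- 0.8 * trait + 0.6 * rnorm(n)   # trait-driven edge
  colnames(edges) <- sprintf("R%d_R%d", c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
  rownames(edges) <- rownames(cf)
  et <- netbridge:::new_edge_table(edges, sprintf("R%d", 1:4),
                                   netbridge:::upper_pairs(4))
  out <- regress_confounds(et, cf)
  X <- netbridge:::confound_design(cf)
  for (j in 2:ncol(X))
    expect_lt(max(abs(cor(out$edges, X[, j]))), 1e-8)
  # idempotence: projecting twice equals projecting once
  out2 <- regress_confounds(out, cf)
  expect_lt(max(abs(out2$edges - out$edges)), 1e-10)
  # planted trait effect (independent of confounds) survives
  expect_lt(abs(cor(out$edges[, 2], trait) - cor(edges[, 2], trait)), 0.05)
  # collinear confounds rejected
  cf_bad <- cf; cf_bad$age_copy <- cf$age
  expect_error(regress_confounds(et, cf_bad), "collinear")
})

test_that("ROI coverage filter uses a strict threshold", {
  cov_frac <- c(A = 0.49, B = 0.50, C = 1.0, D = 0.2)
  f <- filter_rois(cov_frac)
  expect_setequal(f$excluded, c("A", "D"))   # 0.49 out, 0.50 stays
  expect_setequal(f$kept, c("B", "C"))
  expect_identical(filter_rois(c(a = 1, b = 1))$excluded, character(0))
  expect_error(filter_rois(c(a = 1.2)), "\\[0, 1\\]")
  # edge table restriction drops edges touching excluded ROIs
  set.seed(7)
  edges <- matrix(rnorm(5 * 6), 5, 6)
  colnames(edges) <- c("A_B", "A_C", "A_D", "B_C", "B_D", "C_D")
  rownames(edges) <- paste0("s", 1:5)
  et <- netbridge:::new_edge_table(edges, c("A", "B", "C", "D"),
                                   netbridge:::upper_pairs(4))
  f2 <- filter_rois(c(A = 0.4, B = 1, C = 1, D = 1), edges = et)
  expect_identical(colnames(f2$edges$edges), c("B_C", "B_D", "C_D"))
  expect_identical(f2$edges$roi_names, c("B", "C", "D"))
})

test_that("edge-table CSV round-trips", {
  spec <- synth_spec(n_subjects = 12, n_roi = 4, seed = 8)
  et <- make_edge_table(spec, make_behaviour(spec))
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_table(et, path)
  back <- read_edge_table(path, roi_names = et$roi_names)
  expect_equal(back$edges, et$edges, tolerance = 1e-12)
  expect_identical(back$pairs, et$pairs)
})
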
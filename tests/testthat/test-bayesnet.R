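collider_data <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n); y <- rnorm(n); z <- 0.6 * x + 0.6 * y + rnorm(n)
  data.frame(X = x, Y = y, Z = z)
}

chain_data <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- 0.6 * y + rnorm(n)
  data.frame(X = x, Y = y, Z = z)
}

all_algorithms <- c("gs", "iamb", "fast_iamb", "inter_iamb", "mmpc")

test_that("CI tests match their closed forms on exact-correlation data", {
  d <- exact_corr_data(100, matrix(c(1, .5, .5, 1), 2, 2), seed = 1,
                       names = c("a", "b"))
  fz <- ci_test(d, "a", "b", method = "fisher_z")
  expect_equal(fz$statistic, atanh(0.5) * sqrt(97), tolerance = 1e-8)
  pt <- ci_test(d, "a", "b", method = "pearson_t")
  expect_equal(pt$statistic, 0.5 * sqrt(98 / 0.75), tolerance = 1e-8)

  d6 <- exact_corr_data(80, matrix(c(1, .6, .6, 1), 2, 2), seed = 2,
                        names = c("a", "b"))
  mi <- ci_test(d6, "a", "b", method = "mutual_information")
  expect_equal(mi$mi, -0.5 * log(1 - 0.36), tolerance = 1e-8)  # 0.2231 nats
  expect_equal(mi$statistic, 2 * 80 * mi$mi, tolerance = 1e-8)

  mc <- ci_test(d6, "a", "b", method = "mc_permutation", B = 199, seed = 3)
  expect_equal(mc$p_value, 1 / 200)  # r = 0.6 beats every permutation
  expect_identical(mc$p_value,
                   ci_test(d6, "a", "b", method = "mc_permutation",
                           B = 199, seed = 3)$p_value)
})

test_that("conditioning on the middle of a chain removes the dependence", {
  d <- chain_data(1000, 4)
  marg <- ci_test(d, "X", "Z", method = "fisher_z")
  cond <- ci_test(d, "X", "Z", Z = "Y", method = "fisher_z")
  expect_lt(marg$p_value, 1e-6)
  expect_lt(abs(cond$r), 0.1)
  expect_gt(cond$p_value, 0.001)
})

test_that("insufficient degrees of freedom report non-rejection with a warning", {
  d <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5), e = rnorm(5))
  expect_warning(res <- ci_test(d, "a", "b", Z = c("c", "e"),
                                method = "fisher_z"), "insufficient")
  expect_identical(res$p_value, 1)
})

test_that("all five algorithms recover the collider and leave the chain undirected", {
  for (alg in all_algorithms) {
    g <- learn_structure(collider_data(5000, 5), algorithm = alg, alpha = 0.01)
    d <- directed_edges(g)
    expect_identical(nrow(d), 2L)
    expect_setequal(paste(d[, 1], d[, 2]), c("X Z", "Y Z"))
    g2 <- learn_structure(chain_data(5000, 6), algorithm = alg, alpha = 0.01)
    expect_identical(nrow(directed_edges(g2)), 0L)
    u <- undirected_edges(g2)
    expect_setequal(paste(u[, 1], u[, 2]), c("X Y", "Y Z"))
  }
})

test_that("independent columns give the empty graph; output is acyclic", {
  set.seed(7)
  d <- as.data.frame(matrix(rnorm(3000), 1000, 3))
  names(d) <- c("A", "B", "C")
  for (alg in all_algorithms) {
    g <- learn_structure(d, algorithm = alg, alpha = 0.01)
    expect_identical(nrow(directed_edges(g)) + nrow(undirected_edges(g)), 0L)
  }
  expect_error(pdag(c("a", "b", "c"),
                    matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)),
               "cycle")
})

test_that("learned PDAGs match the brute-force CPDAG oracle on 4-node DAGs", {
  # oracle: enumerate every acyclic orientation, keep the Markov-equivalence
  # class by d-separation signature, intersect orientations (8 seeds here;
  # the spec-scale criterion runs in the acceptance suite)
  hits <- 0L
  for (s in 1:8) {
    set.seed(1000 + s)
    dag <- matrix(0, 4, 4)
    ord <- sample(4)
    for (i in 1:3) for (j in (i + 1):4)
      if (runif(1) < 0.5) dag[ord[i], ord[j]] <- 1
    if (sum(dag) == 0) dag[ord[1], ord[2]] <- 1
    d <- oracle_sem_sample(dag, 10000, coef = 0.7, seed = 2000 + s)
    g <- learn_structure(d, algorithm = "iamb", test = "fisher_z", alpha = 0.01)
    learned <- g$amat[paste0("N", 1:4), paste0("N", 1:4)]
    dimnames(learned) <- NULL
    if (identical(learned, oracle_cpdag(dag))) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("MC-permutation learning is deterministic under a fixed seed", {
  d <- collider_data(400, 9)
  g1 <- learn_structure(d, "gs", test = "mc_permutation", B = 99, seed = 5)
  g2 <- learn_structure(d, "gs", test = "mc_permutation", B = 99, seed = 5)
  expect_identical(g1$amat, g2$amat)
})

test_that("consensus keeps unanimous edges and itemizes disagreements", {
  nodes <- c("A", "B", "C")
  a1 <- matrix(0L, 3, 3); a1[1, 2] <- 1L; a1[2, 3] <- a1[3, 2] <- 1L
  g1 <- pdag(nodes, a1)
  expect_identical(consensus_structure(list(g1, g1))$pdag$amat, g1$amat)
  expect_identical(nrow(consensus_structure(list(g1, g1))$disagreements), 0L)
  # one input missing an edge: excluded and reported
  a2 <- a1; a2[2, 3] <- a2[3, 2] <- 0L
  g2 <- pdag(nodes, a2)
  cons <- consensus_structure(list(g1, g2))
  expect_identical(cons$pdag$amat[2, 3], 0L)
  expect_identical(cons$disagreements$kind, "presence")
  # directed vs undirected conflict flagged as orientation disagreement
  a3 <- a1; a3[2, 1] <- 1L
  cons2 <- consensus_structure(list(g1, pdag(nodes, a3)))
  expect_identical(cons2$pdag$amat[1, 2], 0L)
  expect_match(cons2$disagreements$kind, "orientation")
})

test_that("PDAG CSV serialization writes both edge types", {
  nodes <- c("A", "B", "C")
  a <- matrix(0L, 3, 3); a[1, 2] <- 1L; a[2, 3] <- a[3, 2] <- 1L
  path <- withr::local_tempfile(fileext = ".csv")
  write_pdag(pdag(nodes, a), path)
  df <- read.csv(path)
  expect_setequal(df$type, c("directed", "undirected"))
  expect_identical(df$from[df$type == "directed"], "A")
})
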
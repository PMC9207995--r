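# Gaussian graphical models: unregularized maximum likelihood under a fixed
# zero pattern (Dempster conditions), EBIC model scoring, a graphical-lasso
# path to propose candidate supports, greedy stepwise refinement, and
# nonparametric bootstrap edge stability.

support_matrix <- function(p, edges = NULL, nodes = NULL) {
  s <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(edges))
    for (k in seq_len(nrow(edges))) {
      s[edges[k, 1], edges[k, 2]] <- TRUE
      s[edges[k, 2], edges[k, 1]] <- TRUE
    }
  s
}

#' Maximum-likelihood Gaussian graphical model under a fixed support
#'
#' Fits the unregularized GGM whose precision matrix is constrained to zero
#' off the support, by the modified-regression iterative algorithm. At
#' convergence the model covariance satisfies the Dempster conditions: it
#' equals the input matrix on the diagonal and on every support edge, and
#' the precision is exactly zero elsewhere. Partial correlations are
#' \eqn{\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}}.
#'
#' @param corr positive definite covariance/correlation matrix.
#' @param support logical symmetric adjacency matrix (diagonal ignored).
#' @param n sample size behind `corr` (stored for EBIC).
#' @param tol convergence tolerance on the fitted covariance (default 1e-8).
#' @param max_iter sweep limit (default 10000).
#' @return A `ggm_fit`: precision `kappa`, `pcor`, fitted covariance
#'   `sigma`, `support`, log-likelihood `logLik` (up to the model-constant
#'   `2*pi` term), edge count `n_edges`, `n`, `p`.
#' @export
fit_ggm_support <- function(corr, support, n = NULL, tol = 1e-8,
                            max_iter = 10000L) {
  S <- assert_pd(as.matrix(corr), "corr")
  p <- ncol(S)
  nodes <- colnames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(nodes, nodes)
  support <- as.matrix(support)
  stopifnot(dim(support) == c(p, p))
  support <- (support | t(support))
  diag(support) <- FALSE
  W <- S
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      nb <- which(support[, j])
      w_new <- numeric(p - 1L)
      if (length(nb)) {
        W11 <- W[-j, -j, drop = FALSE]
        nb_pos <- match(nb, setdiff(seq_len(p), j))
        beta <- solve(W11[nb_pos, nb_pos, drop = FALSE], S[nb, j])
        w_new <- drop(W11[, nb_pos, drop = FALSE] %*% beta)
      }
      delta <- max(delta, max(abs(W[-j, j] - w_new)))
      W[-j, j] <- w_new
      W[j, -j] <- w_new
    }
    if (delta < tol) break
    if (it == max_iter)
      stopf("constrained GGM fit did not converge in %d iterations (residual %.3g)",
            max_iter, delta)
  }
  # recover the precision column-wise from the final regressions
  K <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (j in seq_len(p)) {
    nb <- which(support[, j])
    if (length(nb)) {
      W11 <- W[-j, -j, drop = FALSE]
      nb_pos <- match(nb, setdiff(seq_len(p), j))
      beta <- solve(W11[nb_pos, nb_pos, drop = FALSE], S[nb, j])
      k_jj <- 1 / (S[j, j] - sum(W[nb, j] * beta))
      K[j, j] <- k_jj
      K[nb, j] <- -beta * k_jj
    } else {
      K[j, j] <- 1 / S[j, j]
    }
  }
  K <- (K + t(K)) / 2
  K[!support & row(K) != col(K)] <- 0
  d <- 1 / sqrt(diag(K))
  pcor <- -K * tcrossprod(d)
  diag(pcor) <- 1
  n_edges <- sum(support[upper.tri(support)])
  ll <- if (!is.null(n)) {
    ld <- determinant(K, logarithm = TRUE)
    (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
  } else NA_real_
  structure(list(kappa = K, pcor = pcor, sigma = W, support = support,
                 nodes = nodes, n = n, p = p, n_edges = n_edges,
                 logLik = ll, iterations = it),
            class = "ggm_fit")
}

#' Extended Bayesian information criterion of a fitted GGM
#'
#' \deqn{EBIC = -2L + E \log n + 4 E \gamma \log p}
#' with log-likelihood L, edge count E, sample size n and node count p. At
#' `gamma = 0` this is the classical BIC. The model-independent
#' \eqn{2\pi} likelihood constant is omitted throughout, which leaves all
#' model comparisons unchanged.
#'
#' @param fit a `ggm_fit` carrying `n`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return Numeric EBIC value.
#' @export
ebic <- function(fit, gamma = 0.5) {
  stopifnot(inherits(fit, "ggm_fit"))
  if (is.null(fit$n) || is.na(fit$logLik))
    stopf("fit carries no sample size; refit with `n`")
  if (gamma < 0) stopf("gamma must be >= 0")
  -2 * fit$logLik + fit$n_edges * log(fit$n) +
    4 * fit$n_edges * gamma * log(fit$p)
}

# One graphical-lasso solve by block coordinate descent (Friedman et al.):
# returns the support of the penalized precision.
glasso_support <- function(S, lambda, tol = 1e-6, max_iter = 500L) {
  p <- ncol(S)
  W <- S
  diag(W) <- diag(S) + lambda
  B <- matrix(0, p - 1L, p)            # per-column lasso coefficients
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      for (pass in 1:100) {
        ch <- 0
        for (k in seq_len(p - 1L)) {
          resid <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          new_b <- sign(resid) * max(abs(resid) - lambda, 0) / W11[k, k]
          ch <- max(ch, abs(new_b - beta[k]))
          beta[k] <- new_b
        }
        if (ch < tol * 0.1) break
      }
      B[, j] <- beta
      w12 <- drop(W11 %*% beta)
      delta <- max(delta, max(abs(W[idx, j] - w12)))
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    stopf("glasso did not converge at lambda = %.4g (residual %.3g)", lambda, delta)
  nz <- abs(B) > 1e-9
  supp <- matrix(FALSE, p, p)
  for (j in seq_len(p)) supp[setdiff(seq_len(p), j), j] <- nz[, j]
  supp <- supp | t(supp)
  diag(supp) <- FALSE
  dimnames(supp) <- dimnames(S)
  supp
}

#' Graphical-lasso regularization path of candidate supports
#'
#' Solves the graphical lasso along a log-spaced penalty path (default 100
#' values from \eqn{\lambda_{max}}, the smallest penalty giving an empty
#' graph, down to \eqn{0.01\,\lambda_{max}}) and returns the distinct edge
#' supports encountered. The empty support is always included.
#'
#' @param corr positive definite correlation matrix (or pass `data`).
#' @param data optional subjects x nodes matrix; its Pearson correlation is
#'   used.
#' @param n_lambda path length (default 100).
#' @param lambda_ratio ratio of smallest to largest penalty (default 0.01).
#' @return List of distinct logical support matrices, sparsest first.
#' @export
glasso_path <- function(corr = NULL, data = NULL, n_lambda = 100L,
                        lambda_ratio = 0.01) {
  if (is.null(corr)) {
    stopifnot(!is.null(data), nrow(data) > 3L)
    corr <- stats::cor(as.matrix(data))
  }
  S <- assert_pd(as.matrix(corr), "corr")
  p <- ncol(S)
  off <- abs(S); diag(off) <- 0
  lambda_max <- max(off)
  if (lambda_max == 0) return(list(support_matrix(p, nodes = colnames(S))))
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_ratio),
                     length.out = n_lambda))
  supports <- list(support_matrix(p, nodes = colnames(S)))  # empty at lambda_max
  seen <- character(1)
  seen[1] <- ""
  for (lam in lambdas[-1L]) {
    supp <- glasso_support(S, lam)
    key <- paste(which(supp[upper.tri(supp)]), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      supports[[length(supports) + 1L]] <- supp
    }
  }
  supports
}

#' Stepwise EBIC refinement of a GGM support
#'
#' Greedy local search over single-edge additions and removals starting
#' from `start` (typically the EBIC-best graphical-lasso solution). Each
#' candidate support is refit as an unregularized constrained MLE; the move
#' with the largest EBIC decrease is accepted (ties broken by lexicographic
#' edge order) until no move improves the criterion.
#'
#' @param corr positive definite correlation matrix.
#' @param n sample size.
#' @param start logical support matrix to start from (default: empty).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return The EBIC-optimal `ggm_fit` found, with its EBIC in `$ebic`.
#' @export
stepwise_select <- function(corr, n, start = NULL, gamma = 0.5) {
  S <- assert_pd(as.matrix(corr), "corr")
  p <- ncol(S)
  current <- if (is.null(start)) support_matrix(p, nodes = colnames(S))
             else { s <- as.matrix(start) | t(as.matrix(start)); diag(s) <- FALSE; s }
  fit <- fit_ggm_support(S, current, n = n)
  best_ebic <- ebic(fit, gamma)
  pairs <- upper_pairs(p)
  repeat {
    move_ebic <- Inf; move_support <- NULL
    for (k in seq_len(nrow(pairs))) {           # lexicographic edge order
      cand <- current
      i <- pairs$i[k]; j <- pairs$j[k]
      cand[i, j] <- cand[j, i] <- !cand[i, j]
      e <- tryCatch(ebic(fit_ggm_support(S, cand, n = n), gamma),
                    error = function(err) Inf)
      if (e < move_ebic - 1e-12) { move_ebic <- e; move_support <- cand }
    }
    if (move_ebic < best_ebic - 1e-9) {
      current <- move_support
      best_ebic <- move_ebic
    } else break
  }
  fit <- fit_ggm_support(S, current, n = n)
  fit$ebic <- best_ebic
  fit$gamma <- gamma
  fit
}

#' Select a GGM by glasso path plus stepwise EBIC refinement
#'
#' The full model-selection recipe: propose candidate supports with
#' [glasso_path()], refit each without regularization, pick the EBIC-best,
#' then refine with [stepwise_select()].
#'
#' @param data subjects x nodes matrix (complete cases used), or pass a
#'   precomputed `corr` with `n`.
#' @inheritParams stepwise_select
#' @return The selected `ggm_fit`.
#' @export
ggm_select <- function(data = NULL, corr = NULL, n = NULL, gamma = 0.5) {
  if (is.null(corr)) {
    m <- as.matrix(data)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    n <- nrow(m)
    corr <- stats::cor(m)
  }
  stopifnot(!is.null(n))
  supports <- glasso_path(corr)
  ebics <- vapply(supports, function(s)
    tryCatch(ebic(fit_ggm_support(corr, s, n = n), gamma),
             error = function(e) Inf), numeric(1))
  stepwise_select(corr, n, start = supports[[which.min(ebics)]], gamma = gamma)
}

#' Bootstrap edge stability of the selected GGM
#'
#' Nonparametric subject resampling; each replicate re-runs the full
#' estimation (glasso path, EBIC, stepwise refinement). Edges absent from a
#' replicate's model contribute weight zero. Reports per-edge bootstrap
#' medians, 2.5/97.5 percentile bounds, and a significance flag (interval
#' excludes zero).
#'
#' @param data subjects x nodes matrix.
#' @param B bootstrap replicates (default 1000; >= 100 required).
#' @param gamma EBIC hyperparameter.
#' @param seed integer seed.
#' @return A `bootstrap_network`: the full-sample `fit` and a per-edge data
#'   frame `edges` (node_a, node_b, weight, median, lo, hi, significant).
#' @export
bootstrap_network <- function(data, B = 1000L, gamma = 0.5, seed = 1L) {
  B <- assert_count(B, "B", min = 100L)
  m <- as.matrix(data)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); p <- ncol(m)
  if (n < p + 2L) stopf("need n >= p + 2 subjects (have %d for %d nodes)", n, p)
  fit <- ggm_select(m, gamma = gamma)
  pairs <- upper_pairs(p)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, B, nrow(pairs))
    failures <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      rep_fit <- tryCatch(ggm_select(m[idx, , drop = FALSE], gamma = gamma),
                          error = function(e) NULL)
      if (is.null(rep_fit)) { failures <- failures + 1L; next }
      out[b, ] <- rep_fit$pcor[cbind(pairs$i, pairs$j)]
    }
    if (failures > 0.1 * B)
      stopf("bootstrap rejected: %d of %d replicate fits failed", failures, B)
    attr(out, "failures") <- failures
    out
  })
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.5, 0.975))
  nodes <- fit$nodes
  edges <- data.frame(
    node_a = nodes[pairs$i], node_b = nodes[pairs$j],
    weight = fit$pcor[cbind(pairs$i, pairs$j)],
    median = qs[2, ], lo = qs[1, ], hi = qs[3, ],
    significant = qs[1, ] > 0 | qs[3, ] < 0)
  structure(list(fit = fit, edges = edges, B = B, seed = seed,
                 failures = attr(draws, "failures"), gamma = gamma),
            class = "bootstrap_network")
}

#' Write a network edge list as CSV (and optionally JSON)
#'
#' @param net a `bootstrap_network` or `ggm_fit`.
#' @param path CSV output path.
#' @export
write_network <- function(net, path) {
  edges <- if (inherits(net, "bootstrap_network")) net$edges else {
    pairs <- upper_pairs(net$p)
    data.frame(node_a = net$nodes[pairs$i], node_b = net$nodes[pairs$j],
               weight = net$pcor[cbind(pairs$i, pairs$j)])
  }
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}
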
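# Constraint-based Bayesian network structure learning over continuous
# (jointly Gaussian) scores: conditional-independence tests on the partial
# correlation, Markov-blanket / parents-children discovery (Grow-Shrink,
# IAMB, Fast-IAMB, Inter-IAMB, MMPC), AND-rule symmetry correction,
# v-structure orientation and Meek rules, plus cross-run consensus.

# Partial correlation of x and y given Z from the joint correlation matrix.
partial_cor <- function(data, x, y, Z = character()) {
  cols <- c(x, y, Z)
  m <- as.matrix(data[, cols, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  r_mat <- stats::cor(m)
  if (length(Z) == 0L) return(list(r = r_mat[1, 2], n = nrow(m)))
  kappa <- solve(r_mat)
  list(r = -kappa[1, 2] / sqrt(kappa[1, 1] * kappa[2, 2]), n = nrow(m))
}

#' Conditional independence test between two continuous variables
#'
#' All four tests operate on the partial correlation r of `x` and `y` given
#' `Z` (computed by inverting the joint correlation matrix, equivalently by
#' residualization):
#' \describe{
#'   \item{pearson_t}{\eqn{t = r\sqrt{(n - |Z| - 2)/(1 - r^2)}}, two-sided
#'     p from the t distribution with \eqn{n - |Z| - 2} df.}
#'   \item{fisher_z}{\eqn{z = \mathrm{atanh}(r)\sqrt{n - |Z| - 3}},
#'     two-sided normal p.}
#'   \item{mc_permutation}{x and y are residualized on Z; the x-residuals
#'     are permuted `B` times and \eqn{p = (1 + \#\{|r^*| \ge |r|\})/(1 + B)}.}
#'   \item{mutual_information}{Gaussian closed form
#'     \eqn{MI = -\tfrac12\ln(1 - r^2)}; statistic \eqn{G = 2 n\, MI},
#'     p from \eqn{\chi^2_1}.}
#' }
#' With insufficient degrees of freedom the test reports p = 1
#' (non-rejecting) with a warning, the skip behaviour constraint learners
#' rely on.
#'
#' @param data data frame or matrix of numeric columns.
#' @param x,y column names (or indices) under test.
#' @param Z conditioning set (possibly empty).
#' @param method one of `"pearson_t"`, `"fisher_z"`, `"mc_permutation"`,
#'   `"mutual_information"`.
#' @param B Monte-Carlo permutations (mc_permutation only; default 199).
#' @param seed seed for the Monte-Carlo draw.
#' @return A `ci_test_result`: `statistic`, `p_value`, `r`, `method`, `n`,
#'   `x`, `y`, `Z`.
#' @export
ci_test <- function(data, x, y, Z = character(),
                    method = c("fisher_z", "pearson_t", "mc_permutation",
                               "mutual_information"),
                    B = 199L, seed = 1L) {
  method <- match.arg(method)
  pc <- partial_cor(data, x, y, Z)
  r <- max(-1, min(1, pc$r))
  n <- pc$n
  k <- length(Z)
  res <- list(x = x, y = y, Z = Z, r = r, n = n, method = method)
  insufficient <- switch(method,
    fisher_z = n - k - 3 < 1,
    pearson_t = n - k - 2 < 1,
    mc_permutation = n - k - 2 < 1,
    mutual_information = n - k - 2 < 1)
  if (insufficient) {
    warnf("ci_test(%s, %s | %s): insufficient degrees of freedom (n = %d); reported as non-rejecting",
          x, y, paste(Z, collapse = ","), n)
    res$statistic <- NA_real_
    res$p_value <- 1
    return(structure(res, class = "ci_test_result"))
  }
  if (method == "pearson_t") {
    df <- n - k - 2
    res$statistic <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    res$p_value <- 2 * stats::pt(abs(res$statistic), df, lower.tail = FALSE)
  } else if (method == "fisher_z") {
    res$statistic <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r))) * sqrt(n - k - 3)
    res$p_value <- 2 * stats::pnorm(abs(res$statistic), lower.tail = FALSE)
  } else if (method == "mutual_information") {
    mi <- -0.5 * log(max(1 - r^2, .Machine$double.eps))
    res$statistic <- 2 * n * mi
    res$mi <- mi
    res$p_value <- stats::pchisq(res$statistic, df = 1, lower.tail = FALSE)
  } else {  # mc_permutation
    cols <- c(x, y, Z)
    m <- as.matrix(data[, cols, drop = FALSE])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    X <- cbind(1, m[, Z, drop = FALSE])
    rx <- stats::resid(stats::lm.fit(X, m[, 1L]))
    ry <- stats::resid(stats::lm.fit(X, m[, 2L]))
    obs <- abs(stats::cor(rx, ry))
    perm <- with_seed(seed, {
      P <- vapply(seq_len(B), function(b) sample(rx), numeric(length(rx)))
      abs(drop(stats::cor(P, ry)))
    })
    res$statistic <- stats::cor(rx, ry)
    res$p_value <- (1 + sum(perm >= obs)) / (1 + B)
  }
  structure(res, class = "ci_test_result")
}

# --- PDAG container ---------------------------------------------------------

#' Partially directed acyclic graph
#'
#' Adjacency coding: `amat[i, j] == 1 && amat[j, i] == 0` means the directed
#' edge i -> j; `amat[i, j] == amat[j, i] == 1` means an undirected edge.
#' The directed subgraph is required to be acyclic.
#'
#' @param nodes character node labels.
#' @param amat integer adjacency matrix in the above coding.
#' @return A `pdag` object.
#' @export
pdag <- function(nodes, amat = NULL) {
  p <- length(nodes)
  if (is.null(amat)) amat <- matrix(0L, p, p)
  dimnames(amat) <- list(nodes, nodes)
  if (any(diag(amat) != 0)) stopf("self-loops are not allowed")
  g <- structure(list(nodes = nodes, amat = amat), class = "pdag")
  if (!directed_acyclic(g)) stopf("directed subgraph contains a cycle")
  g
}

#' @rdname pdag
#' @param g a `pdag`.
#' @return `directed_edges()` / `undirected_edges()`: two-column character
#'   matrices of edges.
#' @export
directed_edges <- function(g) {
  idx <- which(g$amat == 1L & t(g$amat) == 0L, arr.ind = TRUE)
  cbind(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]])
}

#' @rdname pdag
#' @export
undirected_edges <- function(g) {
  idx <- which(g$amat == 1L & t(g$amat) == 1L & upper.tri(g$amat), arr.ind = TRUE)
  cbind(a = g$nodes[idx[, 1]], b = g$nodes[idx[, 2]])
}

# acyclicity of the directed subgraph by repeated sink elimination
directed_acyclic <- function(g) {
  d <- g$amat == 1L & t(g$amat) == 0L
  repeat {
    if (!any(d)) return(TRUE)
    sinks <- which(rowSums(d) == 0 & (colSums(d) > 0 | rowSums(d) > 0))
    live <- which(rowSums(d) > 0 | colSums(d) > 0)
    sinks <- intersect(live, which(rowSums(d) == 0))
    if (!length(sinks)) return(FALSE)
    d[, sinks] <- FALSE
  }
}

would_cycle <- function(amat, i, j) {
  # would orienting i -> j create a directed cycle? (is j ~> i directed?)
  d <- amat == 1L & t(amat) == 0L
  d[i, j] <- FALSE
  reach <- rep(FALSE, nrow(d)); frontier <- j
  while (length(frontier)) {
    reach[frontier] <- TRUE
    nxt <- which(colSums(d[frontier, , drop = FALSE] > 0) > 0)
    frontier <- setdiff(nxt, which(reach))
  }
  reach[i]
}

# --- Markov blanket / parents-children discovery ----------------------------

# Cached p-value oracle: canonical key is the unordered (x, y) pair plus the
# sorted conditioning set, so symmetric queries reuse one test.
make_pfun <- function(data, test, B, seed) {
  cache <- new.env(parent = emptyenv())
  function(x, y, Z) {
    Z <- sort(setdiff(Z, c(x, y)))
    key <- paste(c(sort(c(x, y)), "|", Z), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    mc_seed <- derive_seed(seed, key)
    p <- suppressWarnings(
      ci_test(data, x, y, Z, method = test, B = B, seed = mc_seed)$p_value)
    cache[[key]] <- p
    p
  }
}

mb_grow_shrink <- function(target, nodes, pfun, alpha) {
  mb <- character()
  repeat {                                   # grow: first dependent candidate
    added <- FALSE
    for (x in sort(setdiff(nodes, c(target, mb)))) {
      if (pfun(target, x, mb) < alpha) { mb <- c(mb, x); added <- TRUE; break }
    }
    if (!added) break
  }
  shrink_mb(target, mb, pfun, alpha)
}

shrink_mb <- function(target, mb, pfun, alpha) {
  repeat {
    removed <- FALSE
    for (x in sort(mb)) {
      if (pfun(target, x, setdiff(mb, x)) >= alpha) {
        mb <- setdiff(mb, x); removed <- TRUE; break
      }
    }
    if (!removed) break
  }
  sort(mb)
}

mb_iamb <- function(target, nodes, pfun, alpha, interleave = FALSE) {
  mb <- character()
  repeat {
    cand <- sort(setdiff(nodes, c(target, mb)))
    if (!length(cand)) break
    ps <- vapply(cand, function(x) pfun(target, x, mb), numeric(1))
    if (min(ps) >= alpha) break
    mb <- c(mb, cand[which.min(ps)])         # most associated first
    if (interleave) mb <- shrink_mb(target, mb, pfun, alpha)
  }
  shrink_mb(target, mb, pfun, alpha)
}

# Speculative growing: admit every currently-dependent candidate in one
# batch (sorted by association), then shrink, until a fixed point.
mb_fast_iamb <- function(target, nodes, pfun, alpha) {
  mb <- character()
  repeat {
    cand <- sort(setdiff(nodes, c(target, mb)))
    if (!length(cand)) break
    ps <- vapply(cand, function(x) pfun(target, x, mb), numeric(1))
    batch <- cand[ps < alpha][order(ps[ps < alpha])]
    if (!length(batch)) break
    mb <- shrink_mb(target, c(mb, batch), pfun, alpha)
  }
  mb
}

# MMPC: forward phase adds the candidate with the best worst-case
# association over subsets of the current PC set; backward phase prunes.
pc_mmpc <- function(target, nodes, pfun, alpha) {
  max_p_over_subsets <- function(x, pc) {
    subsets <- all_subsets(pc)
    max(vapply(subsets, function(s) pfun(target, x, s), numeric(1)))
  }
  pc <- character()
  repeat {
    cand <- sort(setdiff(nodes, c(target, pc)))
    if (!length(cand)) break
    mp <- vapply(cand, max_p_over_subsets, numeric(1), pc = pc)
    if (min(mp) >= alpha) break
    pc <- c(pc, cand[which.min(mp)])
  }
  repeat {
    drop <- FALSE
    for (x in sort(pc)) {
      if (max_p_over_subsets(x, setdiff(pc, x)) >= alpha) {
        pc <- setdiff(pc, x); drop <- TRUE; break
      }
    }
    if (!drop) break
  }
  sort(pc)
}

all_subsets <- function(s) {
  if (!length(s)) return(list(character()))
  unlist(lapply(0:length(s), function(k)
    utils::combn(s, k, simplify = FALSE)), recursive = FALSE)
}

# Find the separating subset (drawn from either node's candidate set) with
# the largest p-value; NULL if none reaches alpha.
find_sepset <- function(x, y, cand_x, cand_y, pfun, alpha) {
  best_p <- -Inf; best <- NULL
  for (s in unique(c(all_subsets(sort(cand_x)), all_subsets(sort(cand_y))))) {
    p <- pfun(x, y, s)
    if (p > best_p) { best_p <- p; best <- s }
  }
  if (best_p >= alpha) list(set = best, p = best_p) else NULL
}

#' Learn a Bayesian-network structure from continuous data
#'
#' Runs the named constraint-based algorithm with the chosen conditional
#' independence test: Markov blankets (GS, IAMB, Fast-IAMB, Inter-IAMB) or
#' parents-children sets (MMPC) are discovered per node, symmetry-corrected
#' with the AND rule, the skeleton is pruned by exhaustive separating-set
#' search within the candidate sets, v-structures are oriented (conflicts
#' resolved in favour of the smaller separating p-value, logged), and -
#' except for MMPC, whose scope ends at the skeleton plus v-structures -
#' Meek rules 1-4 are applied to a fixed point. Candidate sets are always
#' iterated in sorted label order, so node order never affects the result.
#'
#' @param data data frame / matrix of numeric columns (complete cases).
#' @param algorithm one of `"gs"`, `"iamb"`, `"fast_iamb"`, `"inter_iamb"`,
#'   `"mmpc"`.
#' @param test CI test passed to [ci_test()].
#' @param alpha test level (default 0.05).
#' @param B Monte-Carlo permutations for the `mc_permutation` test.
#' @param seed seed (relevant for `mc_permutation` only; fixed data + fixed
#'   seed give an identical PDAG).
#' @return A [pdag()].
#' @export
learn_structure <- function(data,
                            algorithm = c("gs", "iamb", "fast_iamb",
                                          "inter_iamb", "mmpc"),
                            test = "fisher_z", alpha = 0.05, B = 199L,
                            seed = 1L) {
  algorithm <- match.arg(algorithm)
  data <- as.data.frame(data)
  nodes <- sort(colnames(data))
  if (length(nodes) < 2L) stopf("need >= 2 nodes")
  if (nrow(data) <= length(nodes) + 3L)
    stopf("need n > number of nodes + 3")
  pfun <- make_pfun(data, test, B, seed)
  cand <- switch(algorithm,
    gs = sapply(nodes, mb_grow_shrink, nodes, pfun, alpha, simplify = FALSE),
    iamb = sapply(nodes, mb_iamb, nodes, pfun, alpha, simplify = FALSE),
    inter_iamb = sapply(nodes, mb_iamb, nodes, pfun, alpha,
                        interleave = TRUE, simplify = FALSE),
    fast_iamb = sapply(nodes, mb_fast_iamb, nodes, pfun, alpha, simplify = FALSE),
    mmpc = sapply(nodes, pc_mmpc, nodes, pfun, alpha, simplify = FALSE))
  # AND-rule symmetry correction
  for (x in nodes) cand[[x]] <- Filter(function(y) x %in% cand[[y]], cand[[x]])
  p <- length(nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  sepsets <- list()
  sep_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  for (xi in seq_len(p - 1L)) for (yi in (xi + 1L):p) {
    x <- nodes[xi]; y <- nodes[yi]
    if (y %in% cand[[x]]) {
      # candidate edge: adjacent unless some subset of either side separates
      sep <- find_sepset(x, y, setdiff(cand[[x]], y), setdiff(cand[[y]], x),
                         pfun, alpha)
      if (is.null(sep)) adj[x, y] <- adj[y, x] <- TRUE
      else sepsets[[sep_key(x, y)]] <- sep
    } else {
      sep <- find_sepset(x, y, setdiff(cand[[x]], y), setdiff(cand[[y]], x),
                         pfun, alpha)
      sepsets[[sep_key(x, y)]] <- sep %||%
        list(set = setdiff(cand[[x]], y), p = NA_real_)
    }
  }
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  amat[adj] <- 1L
  # v-structures: unshielded x - z - y with z outside sepset(x, y); stronger
  # (smaller sepset p) colliders processed first, conflicts logged
  triples <- list()
  for (z in nodes) {
    nb <- nodes[adj[, z]]
    if (length(nb) < 2L) next
    for (pair in utils::combn(nb, 2L, simplify = FALSE)) {
      x <- pair[1]; y <- pair[2]
      if (adj[x, y]) next
      sep <- sepsets[[sep_key(x, y)]]
      if (is.null(sep) || z %in% sep$set) next
      triples[[length(triples) + 1L]] <- list(x = x, y = y, z = z,
                                              p = sep$p %||% 1)
    }
  }
  if (length(triples)) {
    ord <- order(vapply(triples, function(t) t$p, numeric(1)))
    for (t in triples[ord]) {
      xi <- match(t$x, nodes); yi <- match(t$y, nodes); zi <- match(t$z, nodes)
      for (a in c(xi, yi)) {
        if (amat[zi, a] == 1L && amat[a, zi] == 0L) {
          warnf("conflicting v-structure at %s -> %s dropped (resolved by smaller p)",
                t$z, nodes[a])
        } else if (amat[a, zi] == 1L && !would_cycle(amat, a, zi)) {
          amat[a, zi] <- 1L
          amat[zi, a] <- 0L
        }
      }
    }
  }
  if (algorithm != "mmpc") amat <- meek_rules(amat)
  pdag(nodes, amat)
}

# Meek orientation-propagation rules 1-4, applied to a fixed point.
meek_rules <- function(amat) {
  p <- nrow(amat)
  dir_ <- function(i, j) amat[i, j] == 1L && amat[j, i] == 0L
  und_ <- function(i, j) amat[i, j] == 1L && amat[j, i] == 1L
  adj_ <- function(i, j) amat[i, j] == 1L || amat[j, i] == 1L
  orient <- function(i, j) {
    if (!would_cycle(amat, i, j)) { amat[i, j] <<- 1L; amat[j, i] <<- 0L; TRUE }
    else FALSE
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || !und_(i, j)) next
      # R1: k -> i, i - j, k and j nonadjacent  =>  i -> j
      for (k in seq_len(p)) if (k != i && k != j && dir_(k, i) && !adj_(k, j)) {
        if (orient(i, j)) { changed <- TRUE; break }
      }
      if (!und_(i, j)) next
      # R2: i -> k -> j with i - j  =>  i -> j
      for (k in seq_len(p)) if (k != i && k != j && dir_(i, k) && dir_(k, j)) {
        if (orient(i, j)) { changed <- TRUE; break }
      }
      if (!und_(i, j)) next
      # R3: i - k -> j and i - l -> j, k and l nonadjacent  =>  i -> j
      ks <- which(vapply(seq_len(p), function(k)
        k != i && k != j && und_(i, k) && dir_(k, j), logical(1)))
      if (length(ks) >= 2L) {
        for (a in seq_along(ks)) for (b in seq_along(ks)) {
          if (a < b && !adj_(ks[a], ks[b])) {
            if (orient(i, j)) changed <- TRUE
            break
          }
        }
      }
      if (!und_(i, j)) next
      # R4: i - k, k -> l, l -> j, k and j nonadjacent  =>  i -> j
      for (k in seq_len(p)) {
        if (k == i || k == j || !und_(i, k) || adj_(k, j)) next
        for (l in seq_len(p)) if (l != i && l != j && l != k &&
                                  dir_(k, l) && dir_(l, j) && adj_(i, l)) {
          if (orient(i, j)) { changed <- TRUE; break }
        }
      }
    }
    if (!changed) break
  }
  amat
}

#' Consensus over multiple learned structures
#'
#' Keeps an edge iff it is present with the same type and orientation in
#' every input PDAG; every disagreement (missing edge, orientation or type
#' conflict) is itemized in the report.
#'
#' @param pdags list of [pdag()]s over identical node labels.
#' @return List with the consensus `pdag` and a `disagreements` data frame
#'   (node_a, node_b, kind).
#' @export
consensus_structure <- function(pdags) {
  stopifnot(length(pdags) >= 1L)
  nodes <- pdags[[1]]$nodes
  for (g in pdags) if (!identical(g$nodes, nodes))
    stopf("all PDAGs must share node labels")
  p <- length(nodes)
  status <- function(g, i, j) {
    a <- g$amat[i, j]; b <- g$amat[j, i]
    if (a == 1L && b == 1L) "undirected"
    else if (a == 1L) "forward" else if (b == 1L) "backward" else "none"
  }
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  dis <- list()
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    st <- vapply(pdags, status, character(1), i = i, j = j)
    if (all(st == st[1]) && st[1] != "none") {
      if (st[1] == "undirected") amat[i, j] <- amat[j, i] <- 1L
      else if (st[1] == "forward") amat[i, j] <- 1L
      else amat[j, i] <- 1L
    } else if (any(st != "none") && !all(st == st[1])) {
      kind <- if (any(st == "none")) "presence"
              else if ("undirected" %in% st) "orientation (directed vs undirected)"
              else "orientation (direction conflict)"
      dis[[length(dis) + 1L]] <- data.frame(node_a = nodes[i], node_b = nodes[j],
                                            kind = kind,
                                            inputs = paste(st, collapse = "/"))
    }
  }
  list(pdag = pdag(nodes, amat),
       disagreements = if (length(dis)) do.call(rbind, dis)
                       else data.frame(node_a = character(), node_b = character(),
                                       kind = character(), inputs = character()))
}

#' Serialize a PDAG as a CSV edge list
#'
#' Columns `from`, `to`, `type` (`directed` / `undirected`); undirected
#' edges are written once with the lexicographically smaller node first.
#' @param g a `pdag`.
#' @param path output path.
#' @export
write_pdag <- function(g, path) {
  d <- directed_edges(g)
  u <- undirected_edges(g)
  df <- rbind(
    if (nrow(d)) data.frame(from = d[, 1], to = d[, 2], type = "directed"),
    if (nrow(u)) data.frame(from = pmin(u[, 1], u[, 2]),
                            to = pmax(u[, 1], u[, 2]), type = "undirected"))
  if (is.null(df)) df <- data.frame(from = character(), to = character(),
                                    type = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
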
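# Shared fixtures and independent oracles for the test suite.

# Data with an exact sample correlation matrix over arbitrary column names.
exact_corr_data <- function(n, corr, seed = 1L, names = NULL) {
  p <- ncol(corr)
  names <- names %||% colnames(corr) %||% paste0("V", seq_len(p))
  set.seed(seed)
  z <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))
  out <- q %*% chol(corr)
  colnames(out) <- names
  as.data.frame(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Printed three-trait correlation matrix (Social, Communication, RRBI).
trait_corr3 <- function() {
  matrix(c(1, 0.66, 0.38,
           0.66, 1, 0.36,
           0.38, 0.36, 1), 3, 3,
         dimnames = list(c("Social", "Communication", "RRBI"),
                         c("Social", "Communication", "RRBI")))
}

# --- d-separation oracle (independent of the package implementation) --------

# dag: p x p 0/1 matrix, dag[i, j] == 1 means i -> j.
oracle_ancestors <- function(dag, nodes) {
  anc <- nodes
  repeat {
    parents <- which(rowSums(dag[, anc, drop = FALSE]) > 0)
    new <- setdiff(parents, anc)
    if (!length(new)) return(anc)
    anc <- c(anc, new)
  }
}

# Moral-ancestral-graph criterion: x _||_ y | Z iff x and y are separated by
# Z in the moralized subgraph over the ancestral set of {x, y} u Z.
oracle_dsep <- function(dag, x, y, Z) {
  anc <- sort(oracle_ancestors(dag, c(x, y, Z)))
  sub <- dag[anc, anc, drop = FALSE]
  m <- (sub + t(sub)) > 0
  for (child in seq_along(anc)) {               # marry parents
    pa <- which(sub[, child] > 0)
    if (length(pa) >= 2) for (a in pa) for (b in pa) if (a != b) m[a, b] <- TRUE
  }
  zi <- match(intersect(Z, anc), anc)
  m[zi, ] <- FALSE; m[, zi] <- FALSE
  xi <- match(x, anc); yi <- match(y, anc)
  reach <- rep(FALSE, length(anc)); frontier <- xi
  while (length(frontier)) {
    reach[frontier] <- TRUE
    nxt <- which(colSums(m[frontier, , drop = FALSE]) > 0)
    frontier <- setdiff(nxt, which(reach))
  }
  !reach[yi]
}

# Full conditional-independence signature of a DAG over all (x, y | Z).
oracle_ci_signature <- function(dag) {
  p <- nrow(dag)
  sig <- character()
  for (x in seq_len(p - 1)) for (y in (x + 1):p) {
    rest <- setdiff(seq_len(p), c(x, y))
    for (k in 0:length(rest)) for (Z in combn_list(rest, k)) {
      sig <- c(sig, sprintf("%d,%d|%s=%d", x, y, paste(Z, collapse = ","),
                            oracle_dsep(dag, x, y, Z)))
    }
  }
  sig
}

combn_list <- function(s, k) {
  if (k == 0) return(list(integer()))
  if (length(s) < k) return(list())
  utils::combn(s, k, simplify = FALSE)
}

# All DAGs on p nodes (edge states: none / forward / backward per pair).
oracle_all_dags <- function(p) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  dags <- list()
  for (row in seq_len(nrow(states))) {
    dag <- matrix(0, p, p)
    for (k in seq_len(nrow(pairs))) {
      st <- states[row, k]
      if (st == 1) dag[pairs[k, 1], pairs[k, 2]] <- 1
      if (st == 2) dag[pairs[k, 2], pairs[k, 1]] <- 1
    }
    if (is_acyclic_dag(dag)) dags[[length(dags) + 1L]] <- dag
  }
  dags
}

is_acyclic_dag <- function(dag) {
  remaining <- seq_len(nrow(dag))
  while (length(remaining)) {
    indeg <- colSums(dag[remaining, remaining, drop = FALSE])
    roots <- remaining[indeg == 0]
    if (!length(roots)) return(FALSE)
    remaining <- setdiff(remaining, roots)
  }
  TRUE
}

# True CPDAG by brute force: enumerate every DAG with the same
# d-separation signature; an edge is directed in the CPDAG iff it has that
# orientation in every member of the equivalence class.
oracle_cpdag <- function(dag) {
  p <- nrow(dag)
  sig <- paste(oracle_ci_signature(dag), collapse = ";")
  class_members <- Filter(function(d)
    paste(oracle_ci_signature(d), collapse = ";") == sig, oracle_all_dags(p))
  amat <- matrix(0L, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || dag[i, j] + dag[j, i] == 0) next
    fwd <- all(vapply(class_members, function(d) d[i, j] == 1, logical(1)))
    bwd <- all(vapply(class_members, function(d) d[j, i] == 1, logical(1)))
    if (fwd) amat[i, j] <- 1L
    else if (!bwd) { amat[i, j] <- 1L; amat[j, i] <- 1L }
  }
  amat
}

# Sample from a linear Gaussian structural equation model for a DAG.
oracle_sem_sample <- function(dag, n, coef = 0.7, seed = 1L) {
  set.seed(seed)
  p <- nrow(dag)
  order <- integer()
  left <- seq_len(p)
  d <- dag
  while (length(left)) {
    roots <- left[colSums(d[left, left, drop = FALSE]) == 0]
    order <- c(order, roots)
    left <- setdiff(left, roots)
  }
  x <- matrix(0, n, p)
  for (j in order) {
    pa <- which(dag[, j] > 0)
    x[, j] <- rnorm(n) + if (length(pa)) rowSums(coef * x[, pa, drop = FALSE]) else 0
  }
  colnames(x) <- paste0("N", seq_len(p))
  as.data.frame(x)
}

pdag_amat_of <- function(g) {
  a <- g$amat
  dimnames(a) <- NULL
  a
}
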
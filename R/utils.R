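#' @keywords internal
"_PACKAGE"

# --- validation helpers -----------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  as.numeric(x)
}

# Symmetry check with a tolerance appropriate for accumulated rounding.
assert_symmetric <- function(m, name, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("`%s` must be a square matrix", name)
  if (max(abs(m - t(m))) > tol)
    stopf("`%s` must be symmetric (max asymmetry %.3g)", name, max(abs(m - t(m))))
  (m + t(m)) / 2
}

# Positive semi-definiteness; reports the offending eigenvalue on failure.
assert_psd <- function(m, name, tol = 1e-8) {
  m <- assert_symmetric(m, name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stopf("`%s` is not positive semi-definite: smallest eigenvalue %.6g", name, min(ev))
  m
}

assert_pd <- function(m, name, tol = 1e-10) {
  m <- assert_symmetric(m, name, tol = 1e-8)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol)
    stopf("`%s` is not positive definite: smallest eigenvalue %.6g", name, min(ev))
  m
}

# --- seeding ----------------------------------------------------------------

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  seed <- assert_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Stage seeds are a deterministic function of the master seed and a stage
#' label, so individual pipeline stages can be re-run in isolation and still
#' reproduce the full run. The scheme is a fixed multiplicative hash of the
#' label folded into the master seed, reduced modulo 2^31 - 1.
#'
#' @param master master integer seed.
#' @param label character stage label.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  master <- assert_count(master, "master", min = 0L)
  # iterative polynomial hash; every intermediate stays far below 2^53 so
  # double-precision modular arithmetic is exact
  h <- master %% 2147483647
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k + 1) %% 2147483647
  as.integer(h)
}

# --- symmetric matrix functions (eigendecomposition-based) ------------------

sym_fun <- function(m, f) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- f(e$values)
  res <- e$vectors %*% (v * t(e$vectors))
  (res + t(res)) / 2
}

sym_logm <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("matrix logarithm requires a positive definite matrix")
  sym_fun(m, log)
}

sym_expm <- function(m) sym_fun(m, exp)
sym_sqrtm <- function(m) sym_fun(m, sqrt)
sym_invsqrtm <- function(m) sym_fun(m, function(v) 1 / sqrt(v))

# --- misc -------------------------------------------------------------------

# Upper-triangle (i < j) index pairs in row-major order, matching the
# edge-vectorization convention used throughout.
upper_pairs <- function(p) {
  if (p < 2) return(data.frame(i = integer(), j = integer()))
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
  data.frame(i = i, j = j)
}

edge_names <- function(roi_names, pairs) {
  paste(roi_names[pairs$i], roi_names[pairs$j], sep = "_")
}
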
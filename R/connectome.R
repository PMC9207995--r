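#' Set of subject-level connectome matrices
#'
#' @param matrices named list (by subject id) of square symmetric matrices
#'   over a shared ROI list.
#' @param metric one of `"pearson"`, `"partial"`, `"tangent"`,
#'   `"covariance"`, `"synthetic"`.
#' @param gsr logical provenance flag: were the underlying time series
#'   global-signal regressed? (The regression itself happens upstream in
#'   image preprocessing; here it only labels the data channel.)
#' @return An object of class `connectome_set`.
#' @export
connectome_set <- function(matrices, metric = "pearson", gsr = FALSE) {
  if (!length(matrices)) stopf("empty connectome set")
  if (is.null(names(matrices)))
    names(matrices) <- sprintf("sub%04d", seq_along(matrices))
  roi <- colnames(matrices[[1L]]) %||% sprintf("ROI%03d", seq_len(ncol(matrices[[1L]])))
  ids <- names(matrices)
  matrices <- lapply(ids, function(id) {
    m <- assert_symmetric(as.matrix(matrices[[id]]),
                          sprintf("matrix for subject %s", id))
    if (ncol(m) != length(roi))
      stopf("subject %s: ROI count differs from the shared ROI list", id)
    dimnames(m) <- list(roi, roi)
    m
  })
  names(matrices) <- ids
  metric <- match.arg(metric, c("pearson", "partial", "tangent",
                                "covariance", "synthetic"))
  if (metric %in% c("pearson", "partial")) {
    for (id in seq_along(matrices)) {
      m <- matrices[[id]]
      if (max(abs(diag(m) - 1)) > 1e-8 || max(abs(m)) > 1 + 1e-8)
        stopf("subject %d: %s matrices need unit diagonal and entries in [-1, 1]",
              id, metric)
    }
  }
  structure(list(matrices = matrices, subject_ids = names(matrices),
                 roi_names = roi, metric = metric, gsr = isTRUE(gsr)),
            class = "connectome_set")
}

#' Pearson-correlation connectome from one ROI time-series matrix
#'
#' @param ts timepoints x ROIs numeric matrix (>= 3 rows).
#' @return Square symmetric correlation matrix, unit diagonal.
#' @export
connectome_pearson <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stopf("need >= 3 timepoints")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stopf("constant ROI time series: %s", paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 1
  (r + t(r)) / 2
}

# Schaefer-Strimmer analytic shrinkage of the correlation matrix toward the
# identity; returns the shrunk correlation and the shrinkage weight.
shrink_correlation <- function(ts) {
  n <- nrow(ts)
  x <- scale(ts)                       # unit-variance columns
  r <- crossprod(x) / (n - 1)
  w_bar <- r * (n - 1) / n
  # var-hat of r_ij  =  n/(n-1)^3 * sum_k (w_kij - w_bar_ij)^2
  var_r <- (n / (n - 1)^3) * (crossprod(x^2) - n * w_bar^2)
  off <- upper.tri(r)
  lambda <- sum(var_r[off]) / sum(r[off]^2)
  lambda <- min(1, max(0, lambda))
  r_s <- (1 - lambda) * r
  diag(r_s) <- 1
  list(corr = r_s, lambda = lambda)
}

#' Partial-correlation connectome
#'
#' The correlation between each ROI pair after regressing out all remaining
#' ROI time series, computed from the precision matrix:
#' \eqn{\rho_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}\kappa_{jj}}}. By default
#' the correlation matrix is regularized with an analytic shrinkage estimator
#' (Schaefer-Strimmer, toward the identity) so the estimate is well posed
#' even when timepoints do not greatly exceed ROIs; `shrinkage = "none"`
#' inverts the sample correlation directly and is intended for oracle tests.
#'
#' @param ts timepoints x ROIs matrix.
#' @param shrinkage `"auto"` (default) or `"none"`.
#' @return Square symmetric partial-correlation matrix, unit diagonal.
#' @export
connectome_partial <- function(ts, shrinkage = c("auto", "none")) {
  shrinkage <- match.arg(shrinkage)
  ts <- as.matrix(ts)
  p <- ncol(ts)
  if (shrinkage == "none" && nrow(ts) < p + 2L)
    stopf("direct partial correlation needs >= ROIs + 2 timepoints (have %d for %d ROIs)",
          nrow(ts), p)
  r <- if (shrinkage == "auto") shrink_correlation(ts)$corr else connectome_pearson(ts)
  kappa <- tryCatch(solve(r), error = function(e)
    stopf("singular correlation matrix with shrinkage disabled: %s", conditionMessage(e)))
  d <- 1 / sqrt(diag(kappa))
  pc <- -kappa * tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(r)
  (pc + t(pc)) / 2
}

# Geometric (Karcher) mean of SPD matrices by fixed-point iteration on the
# tangent space; tol on the Frobenius norm of the mean log-deviation.
spd_geometric_mean <- function(mats, tol = 1e-8, max_iter = 200L) {
  g <- Reduce(`+`, mats) / length(mats)   # arithmetic mean as starting point
  for (it in seq_len(max_iter)) {
    g_half <- sym_sqrtm(g)
    g_ihalf <- sym_invsqrtm(g)
    s <- Reduce(`+`, lapply(mats, function(m)
      sym_logm(g_ihalf %*% m %*% g_ihalf))) / length(mats)
    g <- g_half %*% sym_expm(s) %*% g_half
    g <- (g + t(g)) / 2
    if (sqrt(sum(s^2)) < tol) return(g)
  }
  stopf("geometric mean did not converge in %d iterations", max_iter)
}

#' Tangent-space embedding of covariance connectomes
#'
#' Models each participant as a deviation from the group average connectome:
#' the group reference \eqn{C_g} is the geometric mean of the subjects'
#' covariance matrices (fixed-point iteration, tolerance 1e-8), and each
#' subject is mapped to the symmetric matrix
#' \eqn{\log(C_g^{-1/2}\, C\, C_g^{-1/2})}. A subject whose covariance
#' equals the reference maps to the zero matrix.
#'
#' @param set a `connectome_set` of symmetric positive definite matrices
#'   (metric `"covariance"` or `"pearson"` treated as covariance).
#' @param reference `"geometric"` (default) or `"logeuclidean"` (arithmetic
#'   mean of matrix logs; cheaper alternative reference).
#' @return A `connectome_set` with metric `"tangent"`; the reference is kept
#'   in the `"reference"` attribute.
#' @export
connectome_tangent <- function(set, reference = c("geometric", "logeuclidean")) {
  stopifnot(inherits(set, "connectome_set"))
  reference <- match.arg(reference)
  for (id in set$subject_ids) {
    ev <- eigen(set$matrices[[id]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stopf("subject %s: matrix not positive definite (min eigenvalue %.3g)", id, min(ev))
  }
  cg <- if (reference == "geometric") spd_geometric_mean(set$matrices)
        else sym_expm(Reduce(`+`, lapply(set$matrices, sym_logm)) / length(set$matrices))
  cg_ihalf <- sym_invsqrtm(cg)
  tangents <- lapply(set$matrices, function(m) {
    t_m <- sym_logm(cg_ihalf %*% m %*% cg_ihalf)
    dimnames(t_m) <- dimnames(m)
    t_m
  })
  out <- connectome_set(tangents, metric = "tangent", gsr = set$gsr)
  attr(out, "reference") <- cg
  out
}

# --- edge tables ------------------------------------------------------------

new_edge_table <- function(edges, roi_names, pairs, metric = "synthetic",
                           gsr = FALSE, confounds_removed = FALSE) {
  structure(list(edges = edges, roi_names = roi_names, pairs = pairs,
                 subject_ids = rownames(edges), metric = metric,
                 gsr = isTRUE(gsr), confounds_removed = isTRUE(confounds_removed)),
            class = "edge_table")
}

#' @export
dim.edge_table <- function(x) dim(x$edges)

#' Vectorize connectomes into a subjects-by-edges table
#'
#' Row-major upper triangle with i < j: a 3-ROI matrix yields the edges
#' (1,2), (1,3), (2,3) in that order; edge columns are named `"ROIi_ROIj"`.
#'
#' @param set a `connectome_set`.
#' @return An `edge_table` with `R (R - 1) / 2` columns.
#' @export
vectorize_edges <- function(set) {
  stopifnot(inherits(set, "connectome_set"))
  p <- length(set$roi_names)
  pairs <- upper_pairs(p)
  idx <- cbind(pairs$i, pairs$j)
  edges <- t(vapply(set$matrices, function(m) m[idx], numeric(nrow(pairs))))
  if (nrow(pairs) == 1L) edges <- matrix(edges, ncol = 1L)
  rownames(edges) <- set$subject_ids
  colnames(edges) <- edge_names(set$roi_names, pairs)
  new_edge_table(edges, set$roi_names, pairs, metric = set$metric, gsr = set$gsr)
}

#' Rebuild symmetric matrices from an edge table
#'
#' Inverse of [vectorize_edges()]. The diagonal is set to 1 for
#' pearson/partial provenance and 0 otherwise.
#'
#' @param table an `edge_table`.
#' @return A `connectome_set`.
#' @export
devectorize_edges <- function(table) {
  stopifnot(inherits(table, "edge_table"))
  p <- length(table$roi_names)
  if (ncol(table$edges) != p * (p - 1) / 2)
    stopf("edge count %d inconsistent with %d ROIs", ncol(table$edges), p)
  diag_val <- if (table$metric %in% c("pearson", "partial")) 1 else 0
  idx <- cbind(table$pairs$i, table$pairs$j)
  mats <- lapply(seq_len(nrow(table$edges)), function(s) {
    m <- matrix(0, p, p, dimnames = list(table$roi_names, table$roi_names))
    m[idx] <- table$edges[s, ]
    m <- m + t(m)
    diag(m) <- diag_val
    m
  })
  names(mats) <- table$subject_ids
  connectome_set(mats, metric = if (table$metric == "synthetic") "synthetic" else table$metric,
                 gsr = table$gsr)
}

#' Regress confounds out of every connectome edge
#'
#' Replaces each edge column by its OLS residual on an intercept plus the
#' confound design: numeric confounds enter as-is, `age` additionally enters
#' squared, and factor columns (acquisition site) enter as k-1 dummy codes.
#' After regression every edge is orthogonal to every confound column. This
#' mirrors the mega-trawl-style edge-wise de-confounding of age, age^2,
#' site, FD, DVARS, ICV and GM volume.
#'
#' The regression is fit on all subjects in the table, which matches the
#' published pipeline but leaks distributional information across
#' cross-validation folds; set `fit_rows` to the training subjects for a
#' leakage-safe variant (a warning notes the deviation from the reference
#' behaviour).
#'
#' @param edges an `edge_table`.
#' @param confounds data frame aligned with the edge-table subjects (matched
#'   by rowname when available, by position otherwise).
#' @param fit_rows optional subject ids to fit on; residuals are still
#'   produced for all rows.
#' @return The `edge_table` with residualized edges and
#'   `confounds_removed = TRUE`.
#' @export
regress_confounds <- function(edges, confounds, fit_rows = NULL) {
  stopifnot(inherits(edges, "edge_table"))
  confounds <- as.data.frame(confounds)
  if (nrow(confounds) != nrow(edges$edges))
    stopf("confound rows (%d) != edge-table subjects (%d)",
          nrow(confounds), nrow(edges$edges))
  if (!is.null(rownames(confounds)) && !is.null(edges$subject_ids) &&
      all(edges$subject_ids %in% rownames(confounds)))
    confounds <- confounds[edges$subject_ids, , drop = FALSE]
  X <- confound_design(confounds)
  if (qr(X)$rank < ncol(X))
    stopf("collinear confounds: design matrix rank %d < %d columns",
          qr(X)$rank, ncol(X))
  rows <- seq_len(nrow(X))
  if (!is.null(fit_rows)) {
    rows <- match(fit_rows, edges$subject_ids)
    if (anyNA(rows)) stopf("fit_rows contains unknown subjects")
    warnf("confound model fit on %d training subjects only (leakage-safe variant)",
          length(rows))
  }
  fit <- qr(X[rows, , drop = FALSE])
  beta <- qr.coef(fit, edges$edges[rows, , drop = FALSE])
  beta[is.na(beta)] <- 0
  res <- edges$edges - X %*% beta
  dimnames(res) <- dimnames(edges$edges)
  out <- edges
  out$edges <- res
  out$confounds_removed <- TRUE
  out
}

confound_design <- function(confounds) {
  cols <- list(Intercept = rep(1, nrow(confounds)))
  for (nm in names(confounds)) {
    v <- confounds[[nm]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      tab <- table(v)
      if (any(tab == 1L))
        warnf("site level(s) with a single subject: %s (dummy fits that subject exactly)",
              paste(names(tab)[tab == 1L], collapse = ", "))
      lev <- levels(droplevels(v))
      for (l in lev[-1L]) cols[[paste0(nm, "_", l)]] <- as.numeric(v == l)
    } else {
      cols[[nm]] <- as.numeric(v)
      if (identical(nm, "age")) cols[["age2"]] <- as.numeric(v)^2
    }
  }
  keep <- vapply(cols, function(x) stats::sd(x) > 0 || all(x == 1), logical(1))
  do.call(cbind, cols[keep])
}

#' Exclude ROIs with insufficient coverage
#'
#' An ROI is excluded iff its coverage fraction (already minimized over
#' participants upstream) is strictly below the threshold; exactly 50%
#' coverage is kept. Optionally restricts an edge table to kept-ROI pairs.
#'
#' @param coverage named numeric vector, one fraction in [0, 1] per ROI.
#' @param threshold exclusion threshold (default 0.5).
#' @param edges optional `edge_table` to subset.
#' @return List with `kept`, `excluded` (ROI name vectors) and, when `edges`
#'   is given, the restricted `edges`.
#' @export
filter_rois <- function(coverage, threshold = 0.5, edges = NULL) {
  if (is.null(names(coverage))) names(coverage) <- sprintf("ROI%03d", seq_along(coverage))
  if (any(coverage < 0 | coverage > 1))
    stopf("coverage fractions must lie in [0, 1]")
  excluded <- names(coverage)[coverage < threshold]   # strict inequality
  kept <- setdiff(names(coverage), excluded)
  out <- list(kept = kept, excluded = excluded)
  if (!is.null(edges)) {
    stopifnot(inherits(edges, "edge_table"))
    keep_idx <- which(edges$roi_names %in% kept)
    keep_edge <- edges$pairs$i %in% keep_idx & edges$pairs$j %in% keep_idx
    sub <- edges
    sub$edges <- edges$edges[, keep_edge, drop = FALSE]
    sub$roi_names <- edges$roi_names[keep_idx]
    sub$pairs <- data.frame(i = match(edges$pairs$i[keep_edge], keep_idx),
                            j = match(edges$pairs$j[keep_edge], keep_idx))
    out$edges <- sub
  }
  out
}

# --- delimited-text I/O -----------------------------------------------------

#' Read / write connectome and time-series matrix files
#'
#' Time series: whitespace/comma-delimited matrix, optional ROI-name header.
#' Connectomes: square matrix preceded by one header line of ROI names.
#' Edge tables: CSV with a `subject_id` column and edge columns named
#' `"i_j"`.
#' @param path file path.
#' @name connectome-io
NULL

#' @rdname connectome-io
#' @export
read_matrix_file <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' @rdname connectome-io
#' @param m matrix to write.
#' @export
write_matrix_file <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname connectome-io
#' @param table an `edge_table`.
#' @export
write_edge_table <- function(table, path) {
  df <- cbind(subject_id = table$subject_ids, as.data.frame(table$edges))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname connectome-io
#' @param roi_names ROI labels for reconstructing the edge index map; the
#'   number of edge columns must equal `R (R - 1) / 2`.
#' @export
read_edge_table <- function(path, roi_names = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df$subject_id)
  df$subject_id <- NULL
  m <- as.matrix(df)
  rownames(m) <- ids
  n_edges <- ncol(m)
  p <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (p != round(p)) stopf("%d edge columns match no integer ROI count", n_edges)
  p <- as.integer(p)
  roi_names <- roi_names %||% sprintf("ROI%03d", seq_len(p))
  new_edge_table(m, roi_names = roi_names, pairs = upper_pairs(p))
}
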
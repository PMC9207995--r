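# Connectome-based predictive modelling: edge selection by per-edge
# correlation with the behaviour score, summed positive/negative brain
# scores, a joint OLS model, nested shuffle-split tuning, consensus edges
# and permutation inference.

# Per-edge Pearson r with y plus the two-sided p from the t transform with
# n - 2 df. Vectorized over edge columns; constant edges get r = NA.
edge_correlations <- function(E, y) {
  keep <- !is.na(y)
  E <- E[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  yc <- y - mean(y)
  Ec <- scale(E, center = TRUE, scale = FALSE)
  ss_e <- colSums(Ec^2)
  r <- as.vector(crossprod(Ec, yc)) / sqrt(ss_e * sum(yc^2))
  r[ss_e == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Select connectome edges associated with a behaviour score
#'
#' Each edge is correlated with `y` (Pearson); the two-sided p-value comes
#' from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2 degrees
#' of freedom. Edges with p below the threshold enter the positive set when
#' r > 0 and the negative set when r < 0.
#'
#' @param edges an `edge_table` or plain subjects x edges matrix.
#' @param y numeric behaviour vector (one value per subject; NAs dropped
#'   pairwise with the whole row).
#' @param p_threshold selection threshold (default 0.001, the tuned value
#'   in the motivating study).
#' @return List with integer vectors `positive` and `negative` (edge column
#'   indices, disjoint) plus the per-edge `r` and `p`.
#' @export
select_edges <- function(edges, y, p_threshold = 0.001) {
  E <- if (inherits(edges, "edge_table")) edges$edges else as.matrix(edges)
  if (length(y) != nrow(E)) stopf("y length != number of subjects")
  if (sum(!is.na(y)) < 4L) stopf("need >= 4 subjects with observed y")
  if (stats::sd(y, na.rm = TRUE) == 0) stopf("y is constant")
  ec <- edge_correlations(E, y)
  if (anyNA(ec$r))
    warnf("%d constant edge column(s) skipped", sum(is.na(ec$r)))
  sel <- !is.na(ec$p) & ec$p < p_threshold
  list(positive = unname(which(sel & ec$r > 0)),
       negative = unname(which(sel & ec$r < 0)),
       r = ec$r, p = ec$p)
}

#' Summed brain scores for positive and negative edge sets
#'
#' @param edges `edge_table` or matrix.
#' @param positive,negative integer edge-column indices; an empty set yields
#'   a zero vector.
#' @return List with numeric vectors `s_pos` and `s_neg`.
#' @export
brain_scores <- function(edges, positive, negative) {
  E <- if (inherits(edges, "edge_table")) edges$edges else as.matrix(edges)
  sum_set <- function(idx) {
    if (!length(idx)) return(rep(0, nrow(E)))
    rowSums(E[, idx, drop = FALSE])
  }
  list(s_pos = sum_set(positive), s_neg = sum_set(negative))
}

#' Fit the CPM regression model
#'
#' Selects edges on the training data, sums them into positive and negative
#' brain scores, and fits the multiple regression
#' \deqn{y = \beta_{Brain+} S_+ + \beta_{Brain-} S_- + X_{Intercept} + \epsilon}
#' by ordinary least squares. When both edge sets come up empty the model
#' degrades to intercept-only (predicting the training mean) and is flagged.
#'
#' @inheritParams select_edges
#' @return A `cpm_model` with the edge sets, coefficients, threshold and
#'   training subject count.
#' @export
fit_cpm <- function(edges, y, p_threshold = 0.001) {
  E <- if (inherits(edges, "edge_table")) edges$edges else as.matrix(edges)
  keep <- !is.na(y)
  if (sum(keep) <= 3L) stopf("need > 3 training subjects after listwise deletion")
  sel <- select_edges(E[keep, , drop = FALSE], y[keep], p_threshold)
  sc <- brain_scores(E[keep, , drop = FALSE], sel$positive, sel$negative)
  X <- cbind(Intercept = rep(1, sum(keep)),
             s_pos = if (length(sel$positive)) sc$s_pos else NULL,
             s_neg = if (length(sel$negative)) sc$s_neg else NULL)
  beta <- qr.coef(qr(X), y[keep])
  model <- list(positive = sel$positive, negative = sel$negative,
                intercept = unname(beta["Intercept"]),
                beta_pos = if ("s_pos" %in% colnames(X)) unname(beta["s_pos"]) else 0,
                beta_neg = if ("s_neg" %in% colnames(X)) unname(beta["s_neg"]) else 0,
                p_threshold = p_threshold, n_train = sum(keep),
                train_mean = mean(y[keep]),
                intercept_only = !length(sel$positive) && !length(sel$negative))
  class(model) <- "cpm_model"
  model
}

#' Predict behaviour scores from a fitted CPM model
#'
#' Applies the training-selected edge sets and coefficients to new subjects.
#' @param object a `cpm_model`.
#' @param edges `edge_table` or matrix with the same edge columns.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.cpm_model <- function(object, edges, ...) {
  E <- if (inherits(edges, "edge_table")) edges$edges else as.matrix(edges)
  if (object$intercept_only) return(rep(object$train_mean, nrow(E)))
  sc <- brain_scores(E, object$positive, object$negative)
  object$intercept + object$beta_pos * sc$s_pos + object$beta_neg * sc$s_neg
}

#' Combined brain score from a fitted CPM model
#'
#' `beta_pos * S_+ + beta_neg * S_-`, the fitted linear combination of the
#' summed edge weights. The intercept is excluded: downstream network
#' estimation only uses correlations, which are shift-invariant. On the
#' training data this score correlates with y exactly at the model's
#' multiple R.
#'
#' @param model a `cpm_model`.
#' @param edges `edge_table` or matrix covering the model's edge sets.
#' @return Numeric score vector.
#' @export
total_brain_score <- function(model, edges) {
  stopifnot(inherits(model, "cpm_model"))
  E <- if (inherits(edges, "edge_table")) edges$edges else as.matrix(edges)
  needed <- c(model$positive, model$negative)
  if (length(needed) && max(needed) > ncol(E))
    stopf("edge table lacks edges required by the model (max index %d of %d)",
          max(needed), ncol(E))
  sc <- brain_scores(E, model$positive, model$negative)
  model$beta_pos * sc$s_pos + model$beta_neg * sc$s_neg
}

# Deterministic shuffle-split assignments: list of train/test index vectors.
outer_splits <- function(n, n_outer, test_fraction, seed) {
  with_seed(seed, lapply(seq_len(n_outer), function(k) {
    test <- sort(sample.int(n, size = max(1L, round(test_fraction * n))))
    list(train = setdiff(seq_len(n), test), test = test)
  }))
}

# Mean held-out correlation of a fixed (channel, p_threshold) pipeline over
# the provided splits; also returns per-split details.
evaluate_splits <- function(E, y, p_threshold, splits, collect = FALSE) {
  rs <- rep(NA_real_, length(splits))
  sels <- if (collect) vector("list", length(splits))
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    model <- fit_cpm(E[sp$train, , drop = FALSE], y[sp$train], p_threshold)
    pred <- predict(model, E[sp$test, , drop = FALSE])
    obs <- y[sp$test]
    ok <- !is.na(obs)
    if (sum(ok) >= 3L && stats::sd(obs[ok]) > 0 && stats::sd(pred[ok]) > 0)
      rs[k] <- stats::cor(pred[ok], obs[ok])
    if (collect) sels[[k]] <- list(positive = model$positive,
                                   negative = model$negative)
  }
  list(r = rs, mean_r = mean(rs, na.rm = TRUE), selections = sels)
}

#' Tune CPM analysis parameters by nested shuffle-split cross-validation
#'
#' Grid search over data channels (ROI resolution x edge metric x GSR
#' status) and edge-selection p-value thresholds. For each grid cell the
#' same `n_outer` seeded 80/20 shuffle splits are evaluated: edges are
#' selected and the model fitted on the training 80%, and the correlation
#' between predicted and observed scores on the held-out 20% is recorded.
#' An inner k-fold cross-validation inside each training set is recorded as
#' a diagnostic of training-sample performance; the deployed per-split model
#' is refit on the full training 80%. The best cell maximizes the mean
#' held-out correlation (ties: smaller ROI resolution, then stricter
#' threshold).
#'
#' @param channels named list of `edge_table`s sharing the subject list;
#'   each table's `roi_names`/`metric`/`gsr` fields describe the channel.
#' @param y behaviour vector.
#' @param p_grid numeric vector of selection thresholds.
#' @param n_outer number of outer shuffle splits (default 10).
#' @param outer_test_fraction held-out fraction (default 0.2).
#' @param inner_folds inner CV folds (default 10; diagnostic only).
#' @param seed integer seed driving the split assignments.
#' @return A `cpm_tuning` object: long results table (`results`), the
#'   `best` cell, and the split assignments.
#' @export
tune_cpm <- function(channels, y, p_grid = c(0.05, 0.01, 0.005, 0.001),
                     n_outer = 10L, outer_test_fraction = 0.2,
                     inner_folds = 10L, seed = 1L) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)))
    names(channels) <- paste0("channel", seq_along(channels))
  n <- nrow(if (inherits(channels[[1]], "edge_table")) channels[[1]]$edges else channels[[1]])
  for (ch in channels) {
    m <- if (inherits(ch, "edge_table")) ch$edges else ch
    if (nrow(m) != n) stopf("all channels must share the subject list")
  }
  splits <- outer_splits(n, assert_count(n_outer, "n_outer"),
                         outer_test_fraction, seed)
  rows <- list()
  for (ch_name in names(channels)) {
    ch <- channels[[ch_name]]
    E <- if (inherits(ch, "edge_table")) ch$edges else as.matrix(ch)
    resol <- if (inherits(ch, "edge_table")) length(ch$roi_names) else NA_integer_
    for (p_thr in p_grid) {
      ev <- evaluate_splits(E, y, p_thr, splits)
      inner <- vapply(splits, function(sp)
        inner_cv_r(E[sp$train, , drop = FALSE], y[sp$train], p_thr,
                   inner_folds, seed), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch_name, resolution = resol, p_threshold = p_thr,
        split = seq_along(splits), held_out_r = ev$r, inner_cv_r = inner)
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(held_out_r ~ channel + resolution + p_threshold,
                          data = results, FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  ord <- order(-agg$held_out_r, agg$resolution, agg$p_threshold)
  best <- agg[ord[1L], ]
  structure(list(results = results, summary = agg, best = best,
                 splits = splits, seed = seed), class = "cpm_tuning")
}

# Inner k-fold CV mean correlation (diagnostic): deterministic fold
# assignment derived from the seed and the training subset size.
inner_cv_r <- function(E, y, p_threshold, folds, seed) {
  n <- nrow(E)
  folds <- min(folds, n)
  assign <- with_seed(derive_seed(seed, paste0("inner", n)),
                      sample(rep_len(seq_len(folds), n)))
  rs <- vapply(seq_len(folds), function(f) {
    tr <- which(assign != f); te <- which(assign == f)
    if (length(te) < 3L || length(tr) < 4L) return(NA_real_)
    model <- tryCatch(fit_cpm(E[tr, , drop = FALSE], y[tr], p_threshold),
                      error = function(e) NULL)
    if (is.null(model)) return(NA_real_)
    pred <- predict(model, E[te, , drop = FALSE])
    if (stats::sd(y[te]) == 0 || stats::sd(pred) == 0) return(NA_real_)
    stats::cor(pred, y[te])
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Consensus edges across cross-validation splits
#'
#' An edge enters the consensus set iff it was selected with the same sign
#' in at least `min_count` of the splits (7 of 10 in the reference
#' analysis). Edges selected with conflicting signs across splits are
#' excluded and reported.
#'
#' @param selections list of per-split selections, each a list with integer
#'   vectors `positive` and `negative`.
#' @param min_count minimum number of splits (default 7).
#' @return A `consensus_edges` object with `positive`, `negative`,
#'   `conflicts` and the per-edge count tables.
#' @export
consensus_edges <- function(selections, min_count = 7L) {
  min_count <- assert_count(min_count, "min_count")
  if (length(selections) < min_count)
    stopf("min_count (%d) exceeds the number of splits (%d)",
          min_count, length(selections))
  pos_all <- unlist(lapply(selections, `[[`, "positive"))
  neg_all <- unlist(lapply(selections, `[[`, "negative"))
  pos_n <- table(pos_all)
  neg_n <- table(neg_all)
  conflicts <- intersect(names(pos_n), names(neg_n))
  pos <- as.integer(setdiff(names(pos_n)[pos_n >= min_count], conflicts))
  neg <- as.integer(setdiff(names(neg_n)[neg_n >= min_count], conflicts))
  if (length(conflicts))
    warnf("edge(s) with conflicting signs across splits excluded: %s",
          paste(conflicts, collapse = ", "))
  structure(list(positive = sort(pos), negative = sort(neg),
                 conflicts = as.integer(conflicts),
                 counts = list(positive = pos_n, negative = neg_n),
                 min_count = min_count, n_splits = length(selections)),
            class = "consensus_edges")
}

#' Permutation test of cross-validated CPM performance
#'
#' The observed statistic is the mean held-out correlation over the outer
#' shuffle splits. Null statistics re-run the identical pipeline -
#' including edge selection, unless `reselect = FALSE` - on row-permuted
#' behaviour scores with the same split assignments. The p-value uses the
#' add-one estimator \eqn{p = (1 + \#\{null \ge observed\}) / (1 + B)},
#' which is valid (sub-uniform) under exchangeability.
#'
#' @inheritParams select_edges
#' @param n_outer,outer_test_fraction outer shuffle-split parameters.
#' @param n_perm number of permutations (5000 in the reference analysis).
#' @param reselect re-run edge selection inside each permutation (default
#'   TRUE; FALSE freezes the observed edge sets, a faster but
#'   selection-leaking variant).
#' @param seed integer seed for splits and permutations.
#' @return List with `p_value`, `observed`, and the null statistics.
#' @export
permutation_test_cpm <- function(edges, y, p_threshold = 0.001,
                                 n_outer = 10L, outer_test_fraction = 0.2,
                                 n_perm = 5000L, reselect = TRUE, seed = 1L) {
  E <- if (inherits(edges, "edge_table")) edges$edges else as.matrix(edges)
  n_perm <- assert_count(n_perm, "n_perm")
  splits <- outer_splits(nrow(E), n_outer, outer_test_fraction,
                         derive_seed(seed, "perm_splits"))
  observed <- evaluate_splits(E, y, p_threshold, splits)$mean_r
  frozen <- if (!reselect) select_edges(E, y, p_threshold)
  nulls <- with_seed(derive_seed(seed, "perm_draws"), {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      if (reselect) {
        evaluate_splits(E, yp, p_threshold, splits)$mean_r
      } else {
        rs <- vapply(splits, function(sp) {
          sc <- brain_scores(E[sp$train, , drop = FALSE],
                             frozen$positive, frozen$negative)
          X <- cbind(1, sc$s_pos, sc$s_neg)
          beta <- qr.coef(qr(X), yp[sp$train])
          beta[is.na(beta)] <- 0
          sct <- brain_scores(E[sp$test, , drop = FALSE],
                              frozen$positive, frozen$negative)
          pred <- beta[1] + beta[2] * sct$s_pos + beta[3] * sct$s_neg
          if (stats::sd(yp[sp$test]) == 0 || stats::sd(pred) == 0) return(NA_real_)
          stats::cor(pred, yp[sp$test])
        }, numeric(1))
        mean(rs, na.rm = TRUE)
      }
    }, numeric(1))
  })
  if (!is.finite(observed)) {
    warnf("observed statistic undefined (every split had an empty selection or constant outcome); permutation p reported as NA")
    return(list(p_value = NA_real_, observed = observed, nulls = nulls,
                n_perm = n_perm))
  }
  p <- (1 + sum(nulls >= observed, na.rm = TRUE)) / (1 + n_perm)
  list(p_value = p, observed = observed, nulls = nulls, n_perm = n_perm)
}
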
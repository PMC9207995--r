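#' Behaviour table of subjects by trait scores
#'
#' A thin data-frame subclass: one row per subject, one numeric column per
#' trait, `NA` for missing scores. Residualized columns appended by the
#' residualization operations carry the suffix `"_resid"` and the fitted
#' [ResidualModel]s are stored in the `"residual_models"` attribute.
#'
#' @param df data frame of numeric trait columns.
#' @param subject_ids character vector of unique subject identifiers
#'   (defaults to existing rownames or `sub0001`, ...).
#' @return An object of classes `behaviour_table` and `data.frame`.
#' @export
behaviour_table <- function(df, subject_ids = NULL) {
  df <- as.data.frame(df)
  if (is.null(subject_ids)) {
    subject_ids <- if (!is.null(rownames(df)) &&
                       !identical(rownames(df), as.character(seq_len(nrow(df)))))
      rownames(df) else sprintf("sub%04d", seq_len(nrow(df)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(df)) stopf("subject_ids length mismatch")
  if (anyDuplicated(subject_ids))
    stopf("duplicate subject ids: %s",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (!all(vapply(df, is.numeric, logical(1))))
    stopf("all trait columns must be numeric")
  bad <- names(df)[colSums(!is.na(df)) < 3L]
  if (length(bad))
    stopf("trait column(s) with fewer than 3 non-missing values: %s",
          paste(bad, collapse = ", "))
  rownames(df) <- subject_ids
  class(df) <- c("behaviour_table", "data.frame")
  df
}

#' @export
subject_ids <- function(x) UseMethod("subject_ids")

#' @export
subject_ids.behaviour_table <- function(x) rownames(x)

#' @export
subject_ids.data.frame <- function(x) rownames(x)

trait_names <- function(table) {
  setdiff(names(table), grep("_resid$", names(table), value = TRUE))
}

# OLS of y on X columns (with intercept) over complete cases; returns the
# residual vector aligned to the input rows (NA where any input was missing).
ols_residual <- function(y, X, target, regressors) {
  keep <- stats::complete.cases(cbind(y, X))
  if (sum(keep) <= ncol(X) + 1L)
    stopf("too few complete cases (%d) to residualize `%s` on %d regressors",
          sum(keep), target, ncol(X))
  Xc <- cbind(Intercept = 1, as.matrix(X)[keep, , drop = FALSE])
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(Xc))]
    stopf("rank-deficient regressor matrix for `%s`: collinear column(s) %s",
          target, paste(colnames(Xc)[drop_idx], collapse = ", "))
  }
  fit <- qr.coef(qrX, y[keep])
  res <- rep(NA_real_, length(y))
  res[keep] <- y[keep] - drop(Xc %*% fit)
  list(residual = res,
       model = structure(list(target = target, regressors = regressors,
                              coefficients = fit[-1L], intercept = fit[[1L]],
                              residuals = res, n_used = sum(keep)),
                         class = "residual_model"))
}

#' Residualize every trait on all other traits (full scheme)
#'
#' Implements the unique-variance construction in which each trait score is
#' regressed, with intercept, on *all* remaining trait scores and replaced by
#' the ordinary-least-squares residual:
#' \deqn{y_A = \beta_B X_B + \beta_C X_C + \dots + X_{Intercept} + \epsilon.}
#' The residual is orthogonal to every other original trait. Rows with a
#' missing value in any trait entering a given regression are dropped from
#' that fit (complete-case); the residual is `NA` there. Residuals stay on
#' the original score scale.
#'
#' Note that full-scheme residuals are generally *not* mutually orthogonal;
#' use [residualize_sequential()] for a Gram-Schmidt orthogonal set.
#'
#' @param table a [behaviour_table()] with at least two traits.
#' @return The table with `<trait>_resid` columns appended; fitted models in
#'   `attr(, "residual_models")`.
#' @export
residualize_full <- function(table) {
  stopifnot(inherits(table, "behaviour_table"))
  traits <- trait_names(table)
  if (length(traits) < 2L) stopf("full residualization needs >= 2 traits")
  models <- list()
  out <- table
  for (tr in traits) {
    others <- setdiff(traits, tr)
    r <- ols_residual(table[[tr]], table[others], tr, others)
    r$model$scheme <- "full"
    out[[paste0(tr, "_resid")]] <- r$residual
    models[[tr]] <- r$model
  }
  attr(out, "residual_models") <- models
  out
}

#' Residualize traits sequentially (Gram-Schmidt scheme)
#'
#' Trait k in `order` is regressed, with intercept, only on the traits
#' *earlier* in the order; the first trait is kept unchanged (its "residual"
#' is the centred original). The resulting residual columns are mutually
#' orthogonal. With order RRBI, Communication, Social this scheme reproduces
#' the published residual correlation pattern of the ADI-R domains, whereas
#' the full scheme matches the regression equation as written; both are
#' provided because the two disagree for correlated traits.
#'
#' @param table a [behaviour_table()].
#' @param order character permutation of the trait labels.
#' @return As [residualize_full()], with `scheme = "sequential"` models.
#' @export
residualize_sequential <- function(table, order = trait_names(table)) {
  stopifnot(inherits(table, "behaviour_table"))
  traits <- trait_names(table)
  if (!setequal(order, traits) || length(order) != length(traits))
    stopf("`order` must be a permutation of the trait labels (%s)",
          paste(traits, collapse = ", "))
  models <- list()
  out <- table
  for (k in seq_along(order)) {
    tr <- order[[k]]
    earlier <- order[seq_len(k - 1L)]
    if (!length(earlier)) {
      y <- table[[tr]]
      res <- y - mean(y, na.rm = TRUE)
      models[[tr]] <- structure(list(target = tr, regressors = character(),
                                     coefficients = numeric(),
                                     intercept = mean(y, na.rm = TRUE),
                                     residuals = res, n_used = sum(!is.na(y)),
                                     scheme = "sequential", order = order),
                                class = "residual_model")
      out[[paste0(tr, "_resid")]] <- res
    } else {
      r <- ols_residual(table[[tr]], table[earlier], tr, earlier)
      r$model$scheme <- "sequential"
      r$model$order <- order
      out[[paste0(tr, "_resid")]] <- r$residual
      models[[tr]] <- r$model
    }
  }
  attr(out, "residual_models") <- models
  out
}

#' Pairwise-complete Pearson correlation table
#'
#' @param table a behaviour table or any numeric data frame / matrix.
#' @param columns optional column subset.
#' @return Symmetric correlation matrix with unit diagonal. Pairs involving
#'   a constant column are `NA` (flagged with a warning), never silently 0.
#' @export
correlation_table <- function(table, columns = NULL) {
  m <- as.matrix(as.data.frame(table)[, columns %||% colnames(table), drop = FALSE])
  if (!is.numeric(m)) stopf("columns must be numeric")
  const <- apply(m, 2L, function(x) stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
  if (any(const))
    warnf("constant column(s) %s: correlations undefined (NA)",
          paste(colnames(m)[const], collapse = ", "))
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write behaviour CSV
#'
#' CSV dialect: header row of trait names, optional first column
#' `subject_id`, one row per subject, empty cell = missing.
#' @param path file path.
#' @return [read_behaviour()] returns a [behaviour_table()].
#' @export
read_behaviour <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- NULL
  if ("subject_id" %in% names(df)) {
    ids <- as.character(df$subject_id)
    df$subject_id <- NULL
  }
  behaviour_table(df, subject_ids = ids)
}

#' @rdname read_behaviour
#' @param table a behaviour table.
#' @export
write_behaviour <- function(table, path) {
  out <- cbind(subject_id = subject_ids(table), as.data.frame(table))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
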
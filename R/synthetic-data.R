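#' Specification for seeded synthetic fixtures
#'
#' Bundles the parameters of the synthetic world that the pipeline is tested
#' against: a behaviour table with a prescribed correlation structure,
#' connectome edge tables with planted edge-trait associations, confound
#' tables with site structure, and ROI time series. The defaults mirror the
#' structure of the motivating study: n = 172 subjects, three trait domains
#' (Social, Communication, RRBI) with pairwise correlations 0.66 / 0.38 /
#' 0.36, and a categorical acquisition-site label.
#'
#' @param n_subjects number of subjects.
#' @param trait_names character vector of trait labels.
#' @param target_corr symmetric positive semi-definite matrix with unit
#'   diagonal; the trait correlation structure to emulate.
#' @param exact_corr if `TRUE`, the *sample* correlation matrix of the
#'   generated scores equals `target_corr` exactly (to numerical precision),
#'   via QR-orthonormalization of a centred Gaussian draw followed by
#'   Cholesky recoloring. If `FALSE`, scores are multivariate normal with
#'   `target_corr` as the population correlation.
#' @param n_roi number of ROIs implied by the edge table
#'   (`n_roi * (n_roi - 1) / 2` edges).
#' @param planted_effects data frame with columns `edge` (1-based edge
#'   index), `trait` (trait label) and `rho` (effect correlation in (-1, 1));
#'   may have zero rows.
#' @param noise_sd positive standard deviation of the edge noise.
#' @param site_levels number of acquisition-site levels.
#' @param seed integer seed; fully determines every generated table.
#' @return An object of class `synth_spec`.
#' @export
#' @examples
#' spec <- synth_spec(n_subjects = 172, seed = 1)
#' beh <- make_behaviour(spec)
#' round(correlation_table(beh), 2)
synth_spec <- function(n_subjects = 172,
                       trait_names = c("Social", "Communication", "RRBI"),
                       target_corr = default_trait_corr(),
                       exact_corr = TRUE,
                       n_roi = 30,
                       planted_effects = data.frame(edge = integer(),
                                                    trait = character(),
                                                    rho = numeric()),
                       noise_sd = 1,
                       site_levels = 19,
                       seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 2L)
  trait_names <- as.character(trait_names)
  if (anyDuplicated(trait_names)) stopf("duplicate trait names")
  target_corr <- assert_psd(as.matrix(target_corr), "target_corr")
  if (nrow(target_corr) != length(trait_names))
    stopf("target_corr dimension (%d) != number of traits (%d)",
          nrow(target_corr), length(trait_names))
  if (max(abs(diag(target_corr) - 1)) > 1e-10)
    stopf("target_corr must have unit diagonal")
  if (max(abs(target_corr)) > 1 + 1e-10)
    stopf("target_corr entries must lie in [-1, 1]")
  dimnames(target_corr) <- list(trait_names, trait_names)
  n_roi <- assert_count(n_roi, "n_roi", min = 2L)
  n_edges <- n_roi * (n_roi - 1L) / 2L
  pe <- as.data.frame(planted_effects)
  if (nrow(pe)) {
    if (!all(c("edge", "trait", "rho") %in% names(pe)))
      stopf("planted_effects needs columns edge, trait, rho")
    if (anyDuplicated(pe$edge))
      stopf("duplicate planted edge indices: %s",
            paste(pe$edge[duplicated(pe$edge)], collapse = ", "))
    if (any(pe$edge < 1 | pe$edge > n_edges))
      stopf("planted edge indices must lie in 1..%d", n_edges)
    if (any(abs(pe$rho) >= 1)) stopf("planted effect rho must lie in (-1, 1)")
    if (!all(pe$trait %in% trait_names))
      stopf("planted traits not in trait_names: %s",
            paste(setdiff(pe$trait, trait_names), collapse = ", "))
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  structure(list(n_subjects = n_subjects, trait_names = trait_names,
                 target_corr = target_corr, exact_corr = isTRUE(exact_corr),
                 n_roi = n_roi, planted_effects = pe, noise_sd = noise_sd,
                 site_levels = assert_count(site_levels, "site_levels"),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "synth_spec")
}

#' Trait correlation structure used as the generator default
#'
#' The 3 x 3 correlation matrix over (Social, Communication, RRBI) with
#' off-diagonals 0.66, 0.38, 0.36.
#' @return A 3 x 3 correlation matrix.
#' @export
default_trait_corr <- function() {
  m <- matrix(c(1, 0.66, 0.38,
                0.66, 1, 0.36,
                0.38, 0.36, 1), 3, 3)
  dimnames(m) <- list(c("Social", "Communication", "RRBI"),
                      c("Social", "Communication", "RRBI"))
  m
}

#' Generate a behaviour table with a prescribed correlation structure
#'
#' With `exact_corr`, a centred Gaussian draw is QR-orthonormalized and
#' recoloured with the Cholesky factor of `target_corr`, so the sample
#' correlation matrix equals the target to within 1e-10 (deterministic
#' reproduction rather than asymptotic convergence). Otherwise the draw is
#' plain multivariate normal.
#'
#' @param spec a [synth_spec()].
#' @return A [behaviour_table()] of `n_subjects` rows.
#' @export
make_behaviour <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- length(spec$trait_names)
  n <- spec$n_subjects
  if (n <= p + 1L)
    stopf("n_subjects (%d) must exceed number of traits + 1 (%d)", n, p + 1L)
  scores <- with_seed(derive_seed(spec$seed, "behaviour"), {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (spec$exact_corr) {
      z <- scale(z, center = TRUE, scale = FALSE)
      q <- qr.Q(qr(z))               # orthonormal, columns mean-zero
      q %*% chol(spec$target_corr)   # sample corr == target exactly
    } else {
      MASS::mvrnorm(n, mu = rep(0, p), Sigma = spec$target_corr)
    }
  })
  colnames(scores) <- spec$trait_names
  behaviour_table(as.data.frame(scores),
                  subject_ids = sprintf("sub%04d", seq_len(n)))
}

#' Generate a connectome edge table with planted edge-trait associations
#'
#' Every edge is a standardized Gaussian column. A planted edge `e` with
#' effect `rho` for trait `t` is constructed as
#' `rho * scale(t) + sqrt(1 - rho^2) * noise`, so its population correlation
#' with the trait is exactly `rho`; all other edges are pure noise.
#'
#' @param spec a [synth_spec()].
#' @param behaviour the behaviour table the planted effects refer to.
#' @return An [edge_table] of `n_subjects` rows and
#'   `n_roi * (n_roi - 1) / 2` edge columns.
#' @export
make_edge_table <- function(spec, behaviour) {
  stopifnot(inherits(spec, "synth_spec"), inherits(behaviour, "behaviour_table"))
  n <- nrow(behaviour)
  if (n != spec$n_subjects)
    stopf("behaviour has %d rows, spec says %d", n, spec$n_subjects)
  pairs <- upper_pairs(spec$n_roi)
  n_edges <- nrow(pairs)
  edges <- with_seed(derive_seed(spec$seed, "edges"), {
    e <- matrix(stats::rnorm(n * n_edges, sd = spec$noise_sd), n, n_edges)
    e <- matrix(as.numeric(scale(e)), n, n_edges)   # standardized, attrs dropped
    for (k in seq_len(nrow(spec$planted_effects))) {
      pe <- spec$planted_effects[k, ]
      tcol <- as.numeric(scale(behaviour[[pe$trait]]))
      e[, pe$edge] <- pe$rho * tcol + sqrt(1 - pe$rho^2) * e[, pe$edge]
    }
    e
  })
  roi_names <- sprintf("ROI%03d", seq_len(spec$n_roi))
  colnames(edges) <- edge_names(roi_names, pairs)
  rownames(edges) <- subject_ids(behaviour)
  new_edge_table(edges, roi_names = roi_names, pairs = pairs,
                 metric = "synthetic", gsr = FALSE)
}

#' Generate per-subject ROI time series
#'
#' Rows are i.i.d. multivariate normal with covariance `roi_cov`; the
#' per-subject Pearson connectome therefore converges to the correlation
#' form of `roi_cov` as the number of timepoints grows.
#'
#' @param n_subjects number of subjects.
#' @param t timepoints per subject; must exceed the number of ROIs so the
#'   downstream partial correlation is well posed.
#' @param roi_cov ROI covariance (positive semi-definite).
#' @param seed integer seed; the same seed reproduces the series bit for bit.
#' @return A list of `t x n_roi` matrices, one per subject.
#' @export
make_timeseries <- function(n_subjects, t, roi_cov, seed) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  t <- assert_count(t, "t", min = 3L)
  roi_cov <- assert_psd(as.matrix(roi_cov), "roi_cov")
  p <- nrow(roi_cov)
  if (t <= p)
    stopf("t (%d) must exceed the number of ROIs (%d): partial correlation downstream would be ill-posed", t, p)
  if (is.null(colnames(roi_cov))) {
    dimnames(roi_cov) <- list(sprintf("ROI%03d", 1:p), sprintf("ROI%03d", 1:p))
  }
  with_seed(assert_count(seed, "seed", min = 0L), {
    lapply(seq_len(n_subjects), function(s) {
      ts <- MASS::mvrnorm(t, mu = rep(0, p), Sigma = roi_cov)
      colnames(ts) <- colnames(roi_cov)
      ts
    })
  })
}

#' Generate a confound table with site structure
#'
#' Columns: `age` (uniform on `age_range`, default 10-21 years, the study's
#' inclusion window), `site` (categorical with `site_levels` levels;
#' regenerated until every level is non-empty), `fd` (mean framewise
#' displacement, mm, lognormal), `dvars` (standardized DVARS, percent,
#' lognormal), `icv` (intracranial volume, mm^3, normal) and `gm` (total
#' grey-matter volume, mm^3, normal). The paper specifies no confound
#' distributions; these are fixture conventions with plausible positive
#' ranges.
#'
#' @param n_subjects number of subjects.
#' @param site_levels number of acquisition sites (>= 1).
#' @param seed integer seed.
#' @param age_range length-2 numeric, inclusive age bounds in years.
#' @return A data frame with rownames `sub0001`, ... and the columns above.
#' @export
make_confounds <- function(n_subjects, site_levels = 19, seed = 1L,
                           age_range = c(10, 21)) {
  n <- assert_count(n_subjects, "n_subjects")
  k <- assert_count(site_levels, "site_levels")
  if (k > n) stopf("site_levels (%d) cannot exceed n_subjects (%d)", k, n)
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2])
  with_seed(assert_count(seed, "seed", min = 0L), {
    site <- sample.int(k, n, replace = TRUE)
    # multinomial occupancy: redraw until every site level is represented
    while (length(unique(site)) < k) site <- sample.int(k, n, replace = TRUE)
    out <- data.frame(
      age   = stats::runif(n, age_range[1], age_range[2]),
      site  = factor(paste0("site", sprintf("%02d", site)),
                     levels = paste0("site", sprintf("%02d", 1:k))),
      fd    = stats::rlnorm(n, meanlog = log(0.15), sdlog = 0.45),
      dvars = stats::rlnorm(n, meanlog = log(1.5), sdlog = 0.35),
      icv   = stats::rnorm(n, mean = 1.5e6, sd = 1.2e5),
      gm    = stats::rnorm(n, mean = 7e5, sd = 6e4)
    )
    rownames(out) <- sprintf("sub%04d", seq_len(n))
    out
  })
}
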
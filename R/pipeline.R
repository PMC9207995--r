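# Pipeline orchestration: run configuration, QC subject filters, the joint
# behaviour + brain-score table, the end-to-end analysis, and the CLI.

log_msg <- function(stage, level, fmt, ..., logfile = NULL) {
  line <- sprintf("[%s] %s: %s", level, stage, sprintf(fmt, ...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

#' Load and validate a run configuration
#'
#' The configuration is a YAML file mirroring the field list below; every
#' field has a default except `seed`. Fields:
#' `seed` (master integer seed), `output_dir`,
#' `inputs` (`behaviour_csv`, `confounds_csv`, named `edge_csv` map of data
#' channels - or `simulate`: `n_subjects`, `n_roi`, `site_levels`,
#' `planted_edges`, `planted_rho`, `planted_trait`),
#' `residualize` (`scheme` = sequential | full, `order`),
#' `qc` (`fd_max` mm, `dvars_max` percent),
#' `cpm` (`p_grid`, `n_outer`, `outer_test_fraction`, `inner_folds`,
#' `min_count`, `n_perm`),
#' `ggm` (`gamma`, `bootstrap_B`),
#' `bayesnet` (`algorithms`, `tests`, `alpha`, `mc_B`).
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    output_dir = "netbridge_out",
    inputs = list(simulate = list(n_subjects = 172, n_roi = 15,
                                  site_levels = 5, planted_edges = integer(),
                                  planted_rho = 0.5,
                                  planted_trait = "Social")),
    residualize = list(scheme = "sequential",
                       order = c("RRBI", "Communication", "Social")),
    qc = list(fd_max = 0.5, dvars_max = 5),
    cpm = list(p_grid = c(0.01, 0.001), n_outer = 10, outer_test_fraction = 0.2,
               inner_folds = 10, min_count = 7, n_perm = 5000),
    ggm = list(gamma = 0.5, bootstrap_B = 0),
    bayesnet = list(algorithms = c("gs", "iamb"), tests = "fisher_z",
                    alpha = 0.05, mc_B = 199))
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seed)) stopf("config must provide `seed`")
  cfg$seed <- assert_count(cfg$seed, "seed", min = 0L)
  for (f in c("fd_max", "dvars_max"))
    if (cfg$qc[[f]] <= 0) stopf("qc$%s must be positive", f)
  for (f in c("behaviour_csv", "confounds_csv"))
    if (!is.null(cfg$inputs[[f]]) && !file.exists(cfg$inputs[[f]]))
      stopf("input file does not exist: %s", cfg$inputs[[f]])
  for (f in cfg$inputs$edge_csv)
    if (!file.exists(f)) stopf("input file does not exist: %s", f)
  class(cfg) <- "run_config"
  cfg
}

#' Quality-control subject filter on motion metrics
#'
#' A subject is excluded iff framewise displacement exceeds `fd_max` (mm) or
#' DVARS exceeds `dvars_max` (percent); both comparisons are strict, so a
#' subject sitting exactly on a threshold is kept. A subject missing either
#' metric is excluded with reason `"missing_qc"`.
#'
#' @param metrics data frame with columns `fd` and `dvars` (rownames =
#'   subject ids).
#' @param fd_max,dvars_max exclusion thresholds (defaults 0.5 mm / 5%).
#' @return List with `kept`, `excluded` (id vectors) and a `reasons` frame.
#' @export
qc_filter_subjects <- function(metrics, fd_max = 0.5, dvars_max = 5) {
  metrics <- as.data.frame(metrics)
  ids <- rownames(metrics) %||% sprintf("sub%04d", seq_len(nrow(metrics)))
  if (!all(c("fd", "dvars") %in% names(metrics)))
    stopf("metrics must have columns `fd` and `dvars`")
  reason <- rep(NA_character_, nrow(metrics))
  miss <- is.na(metrics$fd) | is.na(metrics$dvars)
  reason[miss] <- "missing_qc"
  reason[!miss & metrics$fd > fd_max] <- "fd"
  both <- !miss & metrics$fd > fd_max & metrics$dvars > dvars_max
  reason[!miss & is.na(reason) & metrics$dvars > dvars_max] <- "dvars"
  reason[both] <- "fd+dvars"
  excluded <- ids[!is.na(reason)]
  list(kept = ids[is.na(reason)], excluded = excluded,
       reasons = data.frame(subject_id = excluded,
                            reason = reason[!is.na(reason)]))
}

#' Assemble the joint behaviour + brain-score table
#'
#' Six columns for the canonical three-trait analysis: the trait scores in
#' their given order followed by the corresponding total brain scores
#' (suffix `"_brain"`). Subjects missing any score are dropped and counted.
#'
#' @param behaviour a [behaviour_table()].
#' @param total_scores named list (one per trait, same order as the traits)
#'   of score vectors aligned with the behaviour subjects.
#' @return Data frame of complete-case rows; dropped count in
#'   `attr(, "n_dropped")`.
#' @export
assemble_joint_table <- function(behaviour, total_scores) {
  stopifnot(inherits(behaviour, "behaviour_table"))
  traits <- names(total_scores)
  if (!all(traits %in% trait_names(behaviour)))
    stopf("total_scores traits not in behaviour table: %s",
          paste(setdiff(traits, trait_names(behaviour)), collapse = ", "))
  out <- as.data.frame(behaviour)[, traits, drop = FALSE]
  for (tr in traits) {
    v <- total_scores[[tr]]
    if (length(v) != nrow(out))
      stopf("misaligned subjects for trait %s (%d scores, %d subjects)",
            tr, length(v), nrow(out))
    if (!is.null(names(v))) {
      if (!all(rownames(out) %in% names(v)))
        stopf("misaligned subject ids for trait %s", tr)
      v <- v[rownames(out)]
    }
    out[[paste0(tr, "_brain")]] <- as.numeric(v)
  }
  keep <- stats::complete.cases(out)
  res <- out[keep, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Run the full network-based regression pipeline
#'
#' QC filtering, residualization, per-trait CPM tuning / consensus /
#' permutation inference, total brain scores, the joint six-column table,
#' GGM estimation (behaviour-only, brain-only, combined) and Bayesian
#' network learning with cross-run consensus. Every stage draws its seed
#' deterministically from the master seed, so the whole report is
#' reproducible; the report contains no timestamps and is byte-identical
#' across re-runs with the same config.
#'
#' @param config a [run_config()] (or path to one).
#' @param write write report and artefacts to `config$output_dir`
#'   (default TRUE).
#' @return The `run_report` list (invisibly the same object written to
#'   `report.json`).
#' @export
run_pipeline <- function(config, write = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  report <- list(package_version = as.character(utils::packageVersion("netbridge")),
                 seed = cfg$seed, stages = list())
  out_dir <- cfg$output_dir
  if (write) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- inputs ---------------------------------------------------------------
  log_msg("inputs", "INFO", "loading inputs")
  if (!is.null(cfg$inputs$behaviour_csv)) {
    behaviour <- read_behaviour(cfg$inputs$behaviour_csv)
    confounds <- if (!is.null(cfg$inputs$confounds_csv)) {
      cf <- utils::read.csv(cfg$inputs$confounds_csv, row.names = 1)
      if ("site" %in% names(cf)) cf$site <- factor(cf$site)
      cf
    }
    channels <- lapply(cfg$inputs$edge_csv, read_edge_table)
  } else {
    sim <- cfg$inputs$simulate
    planted <- if (length(sim$planted_edges))
      data.frame(edge = as.integer(sim$planted_edges),
                 trait = sim$planted_trait, rho = sim$planted_rho)
      else data.frame(edge = integer(), trait = character(), rho = numeric())
    spec <- synth_spec(n_subjects = sim$n_subjects, n_roi = sim$n_roi,
                       planted_effects = planted,
                       site_levels = sim$site_levels,
                       seed = derive_seed(cfg$seed, "simulate"))
    behaviour <- make_behaviour(spec)
    confounds <- make_confounds(sim$n_subjects, sim$site_levels,
                                seed = derive_seed(cfg$seed, "confounds"))
    channels <- list(synthetic = make_edge_table(spec, behaviour))
  }
  n_input <- nrow(behaviour)
  report$stages$inputs <- list(status = "ok", n_subjects = n_input,
                               n_channels = length(channels))

  # -- QC -------------------------------------------------------------------
  if (!is.null(confounds) && all(c("fd", "dvars") %in% names(confounds))) {
    qc <- qc_filter_subjects(confounds, cfg$qc$fd_max, cfg$qc$dvars_max)
    keep <- match(qc$kept, subject_ids(behaviour))
    behaviour <- behaviour_table(as.data.frame(behaviour)[keep, , drop = FALSE],
                                 subject_ids = qc$kept)
    confounds <- confounds[qc$kept, , drop = FALSE]
    channels <- lapply(channels, function(ch) {
      ch$edges <- ch$edges[qc$kept, , drop = FALSE]
      ch$subject_ids <- qc$kept
      ch
    })
    report$stages$qc <- list(status = "ok", n_kept = length(qc$kept),
                             n_excluded = length(qc$excluded),
                             reasons = qc$reasons)
    log_msg("qc", "INFO", "kept %d of %d subjects", length(qc$kept), n_input)
  } else {
    report$stages$qc <- list(status = "skipped")
  }

  # -- confound regression --------------------------------------------------
  if (!is.null(confounds)) {
    channels <- lapply(channels, regress_confounds, confounds = confounds)
    report$stages$confounds <- list(status = "ok",
                                    columns = names(confounds))
  } else report$stages$confounds <- list(status = "skipped")

  # -- residualization ------------------------------------------------------
  scheme <- cfg$residualize$scheme
  behaviour <- if (identical(scheme, "full")) residualize_full(behaviour)
               else residualize_sequential(behaviour,
                                           order = cfg$residualize$order)
  report$stages$residualize <- list(status = "ok", scheme = scheme,
                                    order = cfg$residualize$order)
  report$behaviour_correlations <-
    round(correlation_table(behaviour), 6)

  # -- CPM per trait --------------------------------------------------------
  traits <- trait_names(behaviour)
  cpm_out <- list()
  total_scores <- list()
  for (tr in traits) {
    y <- behaviour[[paste0(tr, "_resid")]]
    seed_tr <- derive_seed(cfg$seed, paste0("cpm_", tr))
    tuning <- tune_cpm(channels, y, p_grid = cfg$cpm$p_grid,
                       n_outer = cfg$cpm$n_outer,
                       outer_test_fraction = cfg$cpm$outer_test_fraction,
                       inner_folds = cfg$cpm$inner_folds, seed = seed_tr)
    best <- tuning$best
    E <- channels[[best$channel]]
    ev <- evaluate_splits(E$edges, y, best$p_threshold, tuning$splits,
                          collect = TRUE)
    cons <- suppressWarnings(consensus_edges(ev$selections,
                                             min_count = cfg$cpm$min_count))
    perm <- if (cfg$cpm$n_perm > 0) {
      permutation_test_cpm(E, y, p_threshold = best$p_threshold,
                           n_outer = cfg$cpm$n_outer,
                           outer_test_fraction = cfg$cpm$outer_test_fraction,
                           n_perm = cfg$cpm$n_perm, seed = seed_tr)
    }
    model <- fit_cpm(E, y, p_threshold = best$p_threshold)
    total_scores[[tr]] <- stats::setNames(total_brain_score(model, E),
                                          subject_ids(behaviour))
    cpm_out[[tr]] <- list(
      best = as.list(best), held_out_r = ev$r, mean_held_out_r = ev$mean_r,
      consensus_positive = cons$positive, consensus_negative = cons$negative,
      permutation_p = if (is.null(perm)) "not run" else perm$p_value,
      full_sample = list(n_positive = length(model$positive),
                         n_negative = length(model$negative),
                         beta_pos = model$beta_pos, beta_neg = model$beta_neg))
    log_msg("cpm", "INFO", "%s: mean held-out r = %.3f, perm p = %s", tr,
            ev$mean_r, if (is.null(perm)) "not run" else format(perm$p_value))
  }
  report$cpm <- cpm_out
  report$stages$cpm <- list(status = "ok", traits = traits,
                            n_perm = cfg$cpm$n_perm)

  # -- joint table and GGM networks -----------------------------------------
  joint <- assemble_joint_table(behaviour, total_scores)
  report$joint_correlations <- round(suppressWarnings(stats::cor(joint)), 6)
  report$stages$joint_table <- list(status = "ok", n_rows = nrow(joint),
                                    n_dropped = attr(joint, "n_dropped"))
  gamma <- cfg$ggm$gamma
  # a trait whose CPM model selected no edges has a constant (zero) total
  # brain score; such nodes carry no correlation information and are
  # excluded from network estimation, with a note in the report
  variable_cols <- names(joint)[vapply(joint, function(v) stats::sd(v) > 0,
                                       logical(1))]
  dropped_const <- setdiff(names(joint), variable_cols)
  if (length(dropped_const))
    log_msg("ggm", "WARN", "constant node(s) dropped from networks: %s",
            paste(dropped_const, collapse = ", "))
  networks <- list()
  for (block in list(list(name = "behaviour", cols = traits),
                     list(name = "brain", cols = paste0(traits, "_brain")),
                     list(name = "combined", cols = names(joint)))) {
    nm <- block$name
    block$cols <- intersect(block$cols, variable_cols)
    if (length(block$cols) < 2L) {
      networks[[nm]] <- list(edges = data.frame(), status = "skipped_degenerate")
      next
    }
    networks[[nm]] <- if (cfg$ggm$bootstrap_B >= 100) {
      bn <- bootstrap_network(joint[, block$cols], B = cfg$ggm$bootstrap_B,
                              gamma = gamma,
                              seed = derive_seed(cfg$seed, paste0("ggm_", nm)))
      list(edges = bn$edges, bootstrap_B = bn$B)
    } else {
      fit <- ggm_select(joint[, block$cols], gamma = gamma)
      pairs <- upper_pairs(fit$p)
      list(edges = data.frame(node_a = fit$nodes[pairs$i],
                              node_b = fit$nodes[pairs$j],
                              weight = fit$pcor[cbind(pairs$i, pairs$j)]),
           bootstrap_B = 0)
    }
  }
  report$networks <- networks
  report$stages$ggm <- list(status = "ok", gamma = gamma,
                            bootstrap_B = cfg$ggm$bootstrap_B,
                            dropped_constant = dropped_const)

  # -- Bayesian networks ----------------------------------------------------
  joint_bn <- joint[, variable_cols, drop = FALSE]
  pdags <- list()
  for (alg in cfg$bayesnet$algorithms) for (tst in cfg$bayesnet$tests) {
    key <- paste(alg, tst, sep = "_")
    pdags[[key]] <- learn_structure(joint_bn, algorithm = alg, test = tst,
                                    alpha = cfg$bayesnet$alpha,
                                    B = cfg$bayesnet$mc_B,
                                    seed = derive_seed(cfg$seed, key))
  }
  cons_bn <- consensus_structure(pdags)
  report$bayesnet <- list(
    runs = lapply(pdags, function(g)
      list(directed = directed_edges(g), undirected = undirected_edges(g))),
    consensus = list(directed = directed_edges(cons_bn$pdag),
                     undirected = undirected_edges(cons_bn$pdag)),
    disagreements = cons_bn$disagreements)
  report$stages$bayesnet <- list(status = "ok",
                                 algorithms = cfg$bayesnet$algorithms,
                                 tests = cfg$bayesnet$tests,
                                 alpha = cfg$bayesnet$alpha)

  class(report) <- "run_report"
  if (write) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(report$joint_correlations),
                     file.path(out_dir, "joint_correlations.csv"))
    for (nm in names(networks))
      utils::write.csv(networks[[nm]]$edges,
                       file.path(out_dir, paste0("network_", nm, ".csv")),
                       row.names = FALSE)
    write_pdag(cons_bn$pdag, file.path(out_dir, "pdag_consensus.csv"))
    log_msg("report", "INFO", "report written to %s",
            file.path(out_dir, "report.json"))
  }
  invisible(report)
}

# --- CLI --------------------------------------------------------------------

parse_cli <- function(args) {
  if (!length(args)) return(list(verb = "help", opts = list()))
  verb <- args[[1]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stopf("unexpected argument: %s", a)
    key <- sub("^--", "", a)
    if (i == length(args)) stopf("missing value for --%s", key)
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  list(verb = verb, opts = opts)
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write synthetic inputs), `residualize`, `cpm`,
#' `network`, `dag`, `run` (full pipeline), `report` (print a written
#' report's stage summary). All verbs accept `--config <yaml>` plus optional
#' `--seed` and `--out` overrides. A thin launcher script is installed at
#' `system.file("cli", "netbridge.R", package = "netbridge")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli(args), error = function(e) {
    message(conditionMessage(e)); NULL
  })
  if (is.null(parsed)) return(invisible(1L))
  verb <- parsed$verb
  opts <- parsed$opts
  if (verb %in% c("help", "--help", "-h")) {
    message("usage: netbridge <simulate|residualize|cpm|network|dag|run|report> ",
            "--config <yaml> [--seed <int>] [--out <dir>]")
    return(invisible(0L))
  }
  status <- tryCatch({
    cfg <- run_config(opts$config %||%
                        stopf("--config is required for verb `%s`", verb))
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    switch(verb,
      simulate = {
        sim <- cfg$inputs$simulate
        spec <- synth_spec(n_subjects = sim$n_subjects, n_roi = sim$n_roi,
                           site_levels = sim$site_levels,
                           seed = derive_seed(cfg$seed, "simulate"))
        beh <- make_behaviour(spec)
        write_behaviour(beh, file.path(cfg$output_dir, "behaviour.csv"))
        write_edge_table(make_edge_table(spec, beh),
                         file.path(cfg$output_dir, "edges_synthetic.csv"))
        cf <- make_confounds(sim$n_subjects, sim$site_levels,
                             seed = derive_seed(cfg$seed, "confounds"))
        utils::write.csv(cf, file.path(cfg$output_dir, "confounds.csv"))
      },
      residualize = {
        rep <- run_stage_behaviour(cfg)
        write_behaviour(rep, file.path(cfg$output_dir, "behaviour_residualized.csv"))
      },
      cpm = run_pipeline(cfg),
      network = run_pipeline(cfg),
      dag = run_pipeline(cfg),
      run = run_pipeline(cfg),
      report = {
        rp <- jsonlite::read_json(file.path(cfg$output_dir, "report.json"))
        for (st in names(rp$stages))
          message(sprintf("%-12s %s", st, rp$stages[[st]]$status))
      },
      stopf("unknown verb: %s", verb))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

run_stage_behaviour <- function(cfg) {
  behaviour <- if (!is.null(cfg$inputs$behaviour_csv))
    read_behaviour(cfg$inputs$behaviour_csv)
  else {
    sim <- cfg$inputs$simulate
    make_behaviour(synth_spec(n_subjects = sim$n_subjects,
                              seed = derive_seed(cfg$seed, "simulate")))
  }
  if (identical(cfg$residualize$scheme, "full")) residualize_full(behaviour)
  else residualize_sequential(behaviour, order = cfg$residualize$order)
}
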
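#' Configuration for an end-to-end analysis run
#'
#' Bundles everything a full LD or DD analysis needs: the genotype table
#' (each entry either a [sim_params()] for simulated cohorts, or
#' `list(file = , channels = )` pointing at a DAM monitor file), the name of
#' the single control genotype, the photoperiod, and module options.
#'
#' @param genotypes named list; one entry per genotype.
#' @param control name of the control genotype (must be in `genotypes`).
#' @param regime a [photo_regime()].
#' @param bin_width analysis bin width in minutes (default 30).
#' @param K harmonics for the HMM switching logits.
#' @param rs_threshold rhythmic-strength cutoff.
#' @param startle_correction apply startle correction in the EI stage.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_restarts,gh_nodes optimizer options for the HMM stage.
#' @param run_hmm include the HMM stages (they dominate runtime).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(genotypes, control, regime = photo_regime(),
                            bin_width = 30, K = 2, rs_threshold = 1.5,
                            startle_correction = TRUE, seed = 1,
                            n_restarts = 2, gh_nodes = 7, run_hmm = TRUE) {
  stopifnot(is.list(genotypes))
  if (!length(genotypes)) stop("config error: empty genotype map")
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("config error: genotypes must be named")
  if (!control %in% names(genotypes))
    stop("config error: control genotype '", control, "' not in genotype map")
  structure(list(genotypes = genotypes, control = control, regime = regime,
                 bin_width = bin_width, K = K, rs_threshold = rs_threshold,
                 startle_correction = startle_correction, seed = seed,
                 n_restarts = n_restarts, gh_nodes = gh_nodes,
                 run_hmm = run_hmm),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' JSON layout: top-level `control`, `regime` (fields of [photo_regime()]),
#' options, and `genotypes` — each entry either `{"simulate": {...}}` with
#' [sim_params()] fields or `{"file": "...", "channels": [...]}`.
#' (The environment ships no TOML parser, so configs are JSON.)
#'
#' @param path JSON file.
#' @param base_dir directory against which relative DAM paths are resolved.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path, base_dir = dirname(path)) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  regime <- do.call(photo_regime, j$regime %||% list())
  gens <- lapply(j$genotypes, function(g) {
    if (!is.null(g$simulate)) do.call(sim_params, g$simulate)
    else list(file = file.path(base_dir, g$file), channels = unlist(g$channels))
  })
  names(gens) <- names(j$genotypes)
  opts <- j[setdiff(names(j), c("genotypes", "control", "regime"))]
  do.call(analysis_config,
          c(list(genotypes = gens, control = j$control, regime = regime), opts))
}

# Materialize the annotated series of every genotype (simulating or reading
# DAM files as configured). Returns list genotype -> list of series.
load_cohorts <- function(config) {
  out <- list()
  for (i in seq_along(config$genotypes)) {
    g <- config$genotypes[[i]]
    name <- names(config$genotypes)[i]
    if (inherits(g, "sim_params")) {
      g$genotype <- name
      sim <- simulate_activity(g, config$regime,
                               seed = child_seed(config$seed, i),
                               bin_width = config$bin_width)
      out[[name]] <- sim$series_set
    } else {
      mon <- read_dam_monitor(g$file)
      out[[name]] <- lapply(g$channels, function(ch) {
        s <- bin_counts(mon, ch, config$bin_width,
                        fly_id = sprintf("%s_ch%02d", name, ch),
                        genotype = name)
        annotate_regime(s, config$regime)
      })
    }
  }
  out
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(status = "ok", value = eval.parent(substitute(expr))),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res["status"]
  if (res$status == "failed") {
    report$stages[[name]]$error <- res$error
    message("stage '", name, "' failed: ", res$error)
  } else report[[name]] <- res$value
  report
}

hmm_stage <- function(cohorts, config, segment) {
  slice_seg <- function(ser) series_slice(ser, ser$segment == segment)
  ctrl <- lapply(cohorts[[config$control]], slice_seg)
  emissions <- fit_emissions(ctrl, segment = segment, K = config$K,
                             bin_width = config$bin_width,
                             n_restarts = config$n_restarts,
                             seed = child_seed(config$seed, 101))
  fits <- list(); curves <- list()
  for (g in names(cohorts)) {
    fit <- fit_hmm(lapply(cohorts[[g]], slice_seg), emissions, K = config$K,
                   gh_nodes = config$gh_nodes,
                   n_restarts = config$n_restarts,
                   seed = child_seed(config$seed, 200 + match(g, names(cohorts))))
    fits[[g]] <- fit
    curves[[g]] <- occupancy_curves(fit, genotype = g)
  }
  curves <- do.call(rbind, curves)
  variability <- occupancy_sd_at_peaks(curves, config$control, config$regime,
                                       segment = segment)
  list(emissions = emissions, fits = fits, occupancy = curves,
       variability = variability)
}

#' Run the light:dark (LD) analysis
#'
#' Per genotype: per-fly entrainment indices at both transitions, fraction
#' of entrained flies, and (optionally) the LD HMM stage — control-fixed
#' emissions, random-intercept fits, model-implied occupancy curves and the
#' between-fly SD of active-state occupancy at the morning and evening
#' peaks. Stage failures are recorded in the report and remaining stages
#' still run.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return report list with elements `ei`, `entrained`, `hmm`
#'   (emissions/fits/occupancy/variability), `stages`, `config`.
#' @export
run_ld_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  cohorts <- load_cohorts(config)
  report <- list(analysis = "LD", config = config, stages = list())
  report <- run_stage(report, "ei", {
    do.call(rbind, lapply(cohorts, ei_table,
                          startle_correction = config$startle_correction))
  })
  report <- run_stage(report, "entrained", percent_entrained(report$ei))
  if (config$run_hmm)
    report <- run_stage(report, "hmm", hmm_stage(cohorts, config, "LD"))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the constant-darkness (DD) analysis
#'
#' Per genotype: rhythmicity classification and summary, free-running peak
#' phases on DD days 2-3 for rhythmic flies only, circular summaries with
#' phase coherence (1 / circular SD), Watson goodness-of-fit per group,
#' pairwise equal-concentration tests with Bonferroni adjustment, and
#' (optionally) the DD HMM occupancy-variability stage.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return report list with elements `rhythm`, `rhythm_summary`, `phases`,
#'   `circular`, `tests`, `hmm`, `stages`, `config`.
#' @export
run_dd_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$regime$n_dd_days < 3) stop("need at least 3 DD days")
  cohorts <- load_cohorts(config)
  report <- list(analysis = "DD", config = config, stages = list())
  report <- run_stage(report, "rhythm", {
    do.call(rbind, lapply(cohorts, classify_rhythmicity,
                          rs_threshold = config$rs_threshold))
  })
  report <- run_stage(report, "rhythm_summary", rhythm_summary(report$rhythm))
  report <- run_stage(report, "phases", {
    do.call(rbind, lapply(names(cohorts), function(g) {
      rh <- report$rhythm[report$rhythm$genotype == g, ]
      if (!any(rh$rhythmic)) {
        message("all flies arrhythmic in '", g, "': phase stage skipped")
        return(NULL)
      }
      phase_table(cohorts[[g]], rhythm = rh)
    }))
  })
  report <- run_stage(report, "circular", {
    ph <- report$phases
    if (is.null(ph) || !nrow(ph)) stop("no phases available")
    do.call(rbind, lapply(split(ph, ph$genotype), function(g) {
      if (nrow(g) < 2) return(NULL)
      s <- circular_summary(g$phase)
      w <- watson_gof(g$phase, seed = child_seed(config$seed, 301))
      data.frame(genotype = g$genotype[1], n = s$n, mu = s$mu,
                 median = s$median, Rbar = s$Rbar, circ_sd = s$circ_sd,
                 kappa = s$kappa, coherence = s$coherence,
                 watson_u2 = w$statistic, watson_p = w$p_value)
    }))
  })
  report <- run_stage(report, "tests", {
    ph <- report$phases
    groups <- split(ph$phase, ph$genotype)
    if (length(groups) < 2) {
      message("single genotype: pairwise tests skipped")
      NULL
    } else equal_kappa_pairwise(groups)
  })
  if (config$run_hmm)
    report <- run_stage(report, "hmm", hmm_stage(cohorts, config, "DD"))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Serialize a report: CSV per table, JSON manifest + HMM parameters.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name) {
    if (!is.null(obj) && is.data.frame(obj) && nrow(obj))
      write.csv(obj, file.path(out_dir, name), row.names = FALSE)
  }
  wr(report$ei, "ei.csv")
  wr(report$entrained, "entrained.csv")
  wr(report$rhythm, "rhythm.csv")
  wr(report$rhythm_summary, "rhythm_summary.csv")
  wr(report$phases, "phases.csv")
  wr(report$circular, "circular_summary.csv")
  wr(report$tests, "tests.csv")
  if (!is.null(report$hmm) && report$stages$hmm$status == "ok") {
    wr(report$hmm$occupancy, "occupancy.csv")
    wr(report$hmm$variability, "variability.csv")
    fitj <- lapply(report$hmm$fits, function(f)
      list(beta12 = f$spec$beta12, beta21 = f$spec$beta21,
           sigma_u = f$spec$sigma_u, logLik = f$logLik,
           boundary = f$boundary,
           u_hat = as.data.frame(f$u_hat)))
    fitj$emissions <- list(mu = report$hmm$emissions$mu,
                           phi = report$hmm$emissions$phi,
                           segment = report$hmm$emissions$segment)
    jsonlite::write_json(fitj, file.path(out_dir, "hmm_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    analysis = report$analysis,
    package_version = as.character(utils::packageVersion("circavar")),
    seed = report$config$seed,
    control = report$config$control,
    genotypes = names(report$config$genotypes),
    options = report$config[c("bin_width", "K", "rs_threshold",
                              "startle_correction", "n_restarts",
                              "gh_nodes", "run_hmm")],
    regime = unclass(report$config$regime),
    stages = lapply(report$stages, function(s) s$status))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
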
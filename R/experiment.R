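#' Configuration for the four-condition pattern-separation experiment
#'
#' Bundles every parameter of the end-to-end experiment: the CA1 patch size,
#' the two feedforward pathway geometries with their nominal activity
#' levels, the target output spiking probability, the pair design
#' (pairs per condition, similar-pair fraction), the surrogate weight model,
#' calibration/sweep settings, and the three named seeds from which all
#' randomness derives (`connectivity`, `weights`, `patterns`).
#'
#' @param n_post Number of CA1 cells in the patch.
#' @param pathways Named list (typically `CA3` and `EC`); each element a list
#'   with `n_pre`, `synapses_per_post`, `fanout` and `activity` (nominal
#'   presynaptic activity proportion).
#' @param p_target Target CA1 spiking probability per gamma window
#'   (default 0.14, i.e. a ~7 Hz peak rate over 20 ms windows).
#' @param n_pairs_per_condition Pattern pairs per condition (default 20).
#' @param similar_fraction Fraction of the maximal Hamming distance defining
#'   "similar" pairs (default 0.02).
#' @param seeds List with integer elements `connectivity`, `weights`,
#'   `patterns`.
#' @param scale `"desk"` (runnable) or `"full"` (full-scale reference
#'   parameterization; analytic use only, see [analytic_reference()]).
#' @param weight_distribution,weight_params Surrogate weight model; see
#'   [threshold_surrogate()].
#' @param calib_patterns,calib_tol Calibration settings; see
#'   [calibrate_threshold()].
#' @param run_sweep Also run an activity sweep + Boltzmann fit per pathway
#'   (default TRUE).
#' @param sweep_patterns Patterns per sweep level (default 200).
#' @param sweep_levels Optional explicit sweep levels; default is 11 points
#'   geometrically spanning 0.4x to 2.5x the nominal activity.
#' @return Object of class `experiment_config` (validated).
#' @seealso [make_desk_config()], [run_experiment()]
#' @export
experiment_config <- function(n_post, pathways, p_target = 0.14,
                              n_pairs_per_condition = 20,
                              similar_fraction = 0.02,
                              seeds = list(connectivity = 1L, weights = 2L,
                                           patterns = 3L),
                              scale = c("desk", "full"),
                              weight_distribution = "lognormal",
                              weight_params = NULL,
                              calib_patterns = 50, calib_tol = 0.005,
                              run_sweep = TRUE, sweep_patterns = 200,
                              sweep_levels = NULL) {
  scale <- match.arg(scale)
  pathways <- lapply(pathways, function(p) {
    list(n_pre = as.integer(p$n_pre),
         synapses_per_post = as.integer(p$synapses_per_post),
         fanout = as.integer(p$fanout),
         activity = as.numeric(p$activity))
  })
  seeds <- lapply(seeds, as.integer)
  cfg <- structure(
    list(n_post = as.integer(n_post), pathways = pathways,
         p_target = p_target,
         n_pairs_per_condition = as.integer(n_pairs_per_condition),
         similar_fraction = similar_fraction, seeds = seeds, scale = scale,
         weight_distribution = weight_distribution,
         weight_params = weight_params,
         calib_patterns = as.integer(calib_patterns), calib_tol = calib_tol,
         run_sweep = isTRUE(run_sweep),
         sweep_patterns = as.integer(sweep_patterns),
         sweep_levels = sweep_levels),
    class = "experiment_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' Checks, before any compute: pathway edge-count consistency
#' (`n_pre * fanout` vs `n_post * synapses_per_post`, within one unit per
#' cell), feasibility of the wiring (`synapses_per_post <= n_pre`),
#' feasibility of both pair designs (`similar_hd` and `distinct_hd` within
#' `max_hd`), valid probabilities, and presence of the three named seeds.
#'
#' @param config An [experiment_config()].
#' @return `config`, invisibly; errors describe the first violated check.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  with(config, {
    if (!is_count(n_post, 1)) stop("n_post must be a positive integer")
    if (!(p_target > 0 && p_target < 1)) stop("p_target must be in (0, 1)")
    if (n_pairs_per_condition < 1) stop("need at least one pair per condition")
    if (!(similar_fraction > 0 && similar_fraction <= 1)) {
      stop("similar_fraction must be in (0, 1]")
    }
    req <- c("connectivity", "weights", "patterns")
    if (!all(req %in% names(seeds))) {
      stop("seeds must name connectivity, weights and patterns")
    }
    if (length(pathways) < 1 || is.null(names(pathways))) {
      stop("pathways must be a non-empty named list")
    }
    for (pw in names(pathways)) {
      p <- pathways[[pw]]
      spec <- pathway_spec(pw, p$n_pre, p$synapses_per_post, p$fanout)
      if (spec$synapses_per_post > spec$n_pre) {
        stop(sprintf("pathway %s: more synapse slots than presynaptic cells", pw))
      }
      if (abs(spec$n_pre * as.numeric(spec$fanout) -
                n_post * as.numeric(spec$synapses_per_post)) > n_post) {
        stop(sprintf("pathway %s: fanout inconsistent with edge count", pw))
      }
      if (!(p$activity > 0 && p$activity < 1)) {
        stop(sprintf("pathway %s: activity must be in (0, 1)", pw))
      }
      k <- round(p$activity * p$n_pre)
      if (k < 1 || k >= p$n_pre) {
        stop(sprintf("pathway %s: activity yields infeasible active count", pw))
      }
      for (d in c(similar_hd(p$n_pre, k, similar_fraction),
                  distinct_hd(p$n_pre, k))) {
        if (d > max_hd(p$n_pre, k)) {
          stop(sprintf("pathway %s: target HD %d exceeds max_hd %d",
                       pw, d, max_hd(p$n_pre, k)))
        }
      }
    }
  })
  invisible(config)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s scale: %d CA1 cells, p_target = %.2f\n",
              x$scale, x$n_post, x$p_target))
  for (pw in names(x$pathways)) {
    p <- x$pathways[[pw]]
    cat(sprintf("  %s: n_pre = %d, %d slots/cell, fanout %d, activity %.3g\n",
                pw, p$n_pre, p$synapses_per_post, p$fanout, p$activity))
  }
  cat(sprintf("  %d pairs/condition, similar fraction %.2g, seeds (%d, %d, %d)\n",
              x$n_pairs_per_condition, x$similar_fraction,
              x$seeds$connectivity, x$seeds$weights, x$seeds$patterns))
  invisible(x)
}

#' Desk-scale experiment configuration
#'
#' A self-consistent scaled-down configuration that preserves the
#' qualitative structure of the full-scale circuit — the CA3-like pathway
#' has more synapses per cell and a much larger fan-out than the EC-like
#' pathway, and nominal activity levels sit in the sparse 5–7% range — while
#' running end-to-end in seconds on one CPU: 500 CA1 cells, a CA3-like
#' pathway of 600 cells with 90 slots/cell (fan-out 75) at 5.5% activity,
#' and an EC-like pathway of 1000 cells with 40 slots/cell (fan-out 20) at
#' 6.85% activity.
#'
#' @param seed Integer master seed; the three named seeds are derived from
#'   it deterministically.
#' @param n_pairs_per_condition Pairs per condition (default 20).
#' @param ... Further arguments passed to [experiment_config()].
#' @return A validated `experiment_config` with `scale = "desk"`.
#' @export
make_desk_config <- function(seed = 1, n_pairs_per_condition = 20, ...) {
  experiment_config(
    n_post = 500,
    pathways = list(
      CA3 = list(n_pre = 600, synapses_per_post = 90,
                 fanout = fanout_of(500, 90, 600), activity = 0.055),
      EC = list(n_pre = 1000, synapses_per_post = 40,
                fanout = fanout_of(500, 40, 1000), activity = 0.0685)
    ),
    n_pairs_per_condition = n_pairs_per_condition,
    seeds = list(connectivity = derive_seed(seed, "connectivity"),
                 weights = derive_seed(seed, "weights"),
                 patterns = derive_seed(seed, "patterns")),
    scale = "desk",
    ...
  )
}

#' Full-scale reference configuration
#'
#' The published full-scale parameterization of the circuit: 23,500 CA1
#' cells, 28,009 CA3 cells onto 4407 slots/cell (fan-out 3697) at 5.50%
#' activity, and 45,073 EC cells onto 1918 slots/cell (fan-out 1000) at
#' 6.85% activity. This configuration exists to drive the analytic
#' machinery ([analytic_reference()]) and to document the parameterization;
#' executing it would require the detailed compartmental neuron backend, so
#' [run_experiment()] refuses it.
#'
#' @param seed Integer master seed (recorded, unused analytically).
#' @return A validated `experiment_config` with `scale = "full"`.
#' @export
make_full_scale_config <- function(seed = 1) {
  experiment_config(
    n_post = 23500,
    pathways = list(
      CA3 = list(n_pre = 28009, synapses_per_post = 4407, fanout = 3697,
                 activity = 1540 / 28009),
      EC = list(n_pre = 45073, synapses_per_post = 1918, fanout = 1000,
                activity = 3086 / 45073)
    ),
    seeds = list(connectivity = derive_seed(seed, "connectivity"),
                 weights = derive_seed(seed, "weights"),
                 patterns = derive_seed(seed, "patterns")),
    scale = "full"
  )
}

#' Analytic reference numbers for a configuration
#'
#' Computes, in closed form and without any simulation, the full set of
#' analytic quantities for a configuration: per pathway the active-cell
#' count, maximal/similar/distinct target Hamming distances, the binomial
#' input-HD statistics, and the percent relative SD of the active-synapse
#' count per cell; for the output population, the chance-level HD statistics
#' at `p_target` in both exact and printed-precision modes, and the expected
#' number of spiking cells.
#'
#' @param config An [experiment_config()] (desk or full scale).
#' @return List with elements `pathways` (data.frame, one row per pathway)
#'   and `output` (list: `n_post`, `p_target`, `spiking_cells`, `stats_exact`,
#'   `stats_printed`).
#' @export
analytic_reference <- function(config) {
  validate_config(config)
  rows <- lapply(names(config$pathways), function(pw) {
    p <- config$pathways[[pw]]
    k <- as.integer(round(p$activity * p$n_pre))
    st <- binomial_hd_stats(p$n_pre, k / p$n_pre)
    data.frame(
      pathway = pw, n_pre = p$n_pre,
      synapses_per_post = p$synapses_per_post, fanout = p$fanout,
      activity = p$activity, k = k,
      max_hd = max_hd(p$n_pre, k),
      similar_hd = similar_hd(p$n_pre, k, config$similar_fraction),
      distinct_hd = distinct_hd(p$n_pre, k),
      input_mean_hd = st$mean_hd, input_sd_hd = st$sd_hd,
      pr_hd = st$pr_hd,
      rel_sd_active_pct = relative_sd_active(k / p$n_pre,
                                             p$synapses_per_post)
    )
  })
  list(
    pathways = do.call(rbind, rows),
    output = list(
      n_post = config$n_post,
      p_target = config$p_target,
      spiking_cells = as.integer(round(config$p_target * config$n_post)),
      stats_exact = binomial_hd_stats(config$n_post, config$p_target),
      stats_printed = binomial_hd_stats(config$n_post, config$p_target,
                                        rounding = "printed")
    )
  )
}

#' Run the four-condition pattern-separation experiment
#'
#' Executes the whole pipeline at the configured scale: builds the frozen
#' random projections, draws the frozen surrogate weights, calibrates the
#' threshold per pathway at its nominal activity to the target spiking
#' probability, optionally sweeps activity and fits a Boltzmann curve per
#' pathway, then for each condition (distinct and similar pairs, each
#' pathway driven alone) generates input pairs at exactly the target Hamming
#' distance, computes the CA1 output pattern of every input, and summarizes
#' the empirical output Hamming distances against the analytic chance level
#' at `p_target`. Fully reproducible: all randomness derives from the three
#' named config seeds.
#'
#' @param config An [experiment_config()] with `scale = "desk"`.
#' @return Object of class `ca1_experiment`: fields `config`, `maps`,
#'   `model` (calibrated per-pathway thetas in `calibrations`), `sweeps`,
#'   `fits`, `activity_at_target`, `conditions` (named
#'   `<pathway>.<condition>`, each with input pairs, output patterns, output
#'   counts, `hd_summary` and the analytic reference), `analytic`.
#' @export
run_experiment <- function(config) {
  validate_config(config)
  if (config$scale == "full") {
    stop(paste("the full-scale configuration is analytic-only (its execution",
               "requires a detailed compartmental backend); use",
               "analytic_reference(), or make_desk_config() to simulate"))
  }
  maps <- lapply(names(config$pathways), function(pw) {
    p <- config$pathways[[pw]]
    build_projection(pathway_spec(pw, p$n_pre, p$synapses_per_post, p$fanout),
                     config$n_post,
                     seed = derive_seed(config$seeds$connectivity, pw))
  })
  names(maps) <- names(config$pathways)
  model <- threshold_surrogate(
    maps, theta = 1,
    weight_distribution = config$weight_distribution,
    weight_params = config$weight_params,
    seed = config$seeds$weights
  )
  calibrations <- list()
  sweeps <- list()
  fits <- list()
  activity_at_target <- list()
  for (pw in names(maps)) {
    act <- config$pathways[[pw]]$activity
    calibrations[[pw]] <- calibrate_threshold(
      model, pw, act, config$p_target,
      n_patterns = config$calib_patterns, tol = config$calib_tol,
      seed = derive_seed(config$seeds$patterns, paste0("calib.", pw))
    )
    if (config$run_sweep) {
      model_pw <- set_theta(model, calibrations[[pw]]$theta)
      levels <- config$sweep_levels %||%
        pmin(0.999, act * exp(seq(log(0.4), log(2.5), length.out = 11)))
      sweeps[[pw]] <- sweep_activity(
        model_pw, pw, levels, n_patterns = config$sweep_patterns,
        seed = derive_seed(config$seeds$patterns, paste0("sweep.", pw))
      )
      fits[[pw]] <- tryCatch(fit_boltzmann(sweeps[[pw]]),
                             error = function(e) NULL)
      activity_at_target[[pw]] <- if (!is.null(fits[[pw]])) {
        invert_for_target(fits[[pw]], config$p_target)
      } else {
        NA_real_
      }
    }
  }
  out_stats <- binomial_hd_stats(config$n_post, config$p_target)
  conditions <- list()
  for (pw in names(maps)) {
    p <- config$pathways[[pw]]
    k <- as.integer(round(p$activity * p$n_pre))
    model_pw <- set_theta(model, calibrations[[pw]]$theta)
    for (cond in c("distinct", "similar")) {
      d <- if (cond == "distinct") distinct_hd(p$n_pre, k)
           else similar_hd(p$n_pre, k, config$similar_fraction)
      pair_seeds <- vapply(seq_len(config$n_pairs_per_condition),
                           function(j) derive_seed(config$seeds$patterns,
                                                   paste(pw, cond, sep = "."),
                                                   j),
                           integer(1))
      pairs <- lapply(seq_len(config$n_pairs_per_condition), function(j) {
        pair_with_hd(p$n_pre, k, d, seed = pair_seeds[j], condition = cond)
      })
      outputs <- lapply(pairs, function(pr) {
        list(
          a = population_response(model_pw,
                                  stats::setNames(list(pr$a), pw)),
          b = population_response(model_pw,
                                  stats::setNames(list(pr$b), pw))
        )
      })
      counts <- unlist(lapply(outputs, function(o) c(o$a$k, o$b$k)))
      stopifnot(all(vapply(outputs, function(o)
        o$a$length == config$n_post && o$b$length == config$n_post, TRUE)))
      conditions[[paste(pw, cond, sep = ".")]] <- list(
        pathway = pw, condition = cond, input_hd = d,
        input_k = k, n_pairs = length(pairs),
        pair_seeds = pair_seeds,
        pairs = pairs, outputs = outputs,
        output_counts = counts,
        hd_summary = empirical_hd_summary(outputs, stats = out_stats)
      )
    }
  }
  structure(
    list(config = config, maps = maps, model = model,
         calibrations = calibrations, sweeps = sweeps, fits = fits,
         activity_at_target = activity_at_target,
         conditions = conditions,
         analytic = analytic_reference(config)),
    class = "ca1_experiment"
  )
}

#' Condition-level report of an experiment
#'
#' Builds the condition x summary table — empirical output Hamming-distance
#' mean and SD, output spike counts, the analytic chance-level reference,
#' and the separation ratio — plus per-condition histograms. The separation
#' ratio is the relative (fraction-of-maximal) output distance divided by
#' the relative input distance; values above 1 mean the patch pushed the
#' patterns further apart, in relative terms, than they came in.
#'
#' @param result A [run_experiment()] result.
#' @param dir Optional directory: when given, writes `report.csv`,
#'   per-condition histogram CSVs and a `provenance.json` with the full
#'   configuration, seeds and calibration outcomes.
#' @return List with `table` (data.frame) and `histograms` (named list of
#'   data.frames), invisibly when `dir` is given.
#' @export
report <- function(result, dir = NULL) {
  stopifnot(inherits(result, "ca1_experiment"))
  expected <- as.vector(outer(names(result$config$pathways),
                              c("distinct", "similar"), paste, sep = "."))
  if (!all(expected %in% names(result$conditions))) {
    stop("incomplete result: missing conditions ",
         paste(setdiff(expected, names(result$conditions)), collapse = ", "))
  }
  cfg <- result$config
  max_out <- 2 * cfg$p_target * cfg$n_post
  rows <- lapply(result$conditions, function(cc) {
    p <- cfg$pathways[[cc$pathway]]
    s <- cc$hd_summary
    data.frame(
      pathway = cc$pathway, condition = cc$condition,
      n_pairs = cc$n_pairs,
      input_hd = cc$input_hd,
      input_rel = cc$input_hd / max_hd(p$n_pre, cc$input_k),
      mean_output_spikes = mean(cc$output_counts),
      sd_output_spikes = stats::sd(cc$output_counts),
      mean_hd = s$mean, sd_hd = s$sd,
      analytic_mean = s$stats$mean_hd, analytic_sd = s$stats$sd_hd,
      separation_ratio = (s$mean / max_out) /
        (cc$input_hd / max_hd(p$n_pre, cc$input_k))
    )
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  hists <- lapply(result$conditions, function(cc) cc$hd_summary$histogram)
  out <- list(table = tab, histograms = hists)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(dir, "report.csv"), row.names = FALSE,
                     quote = FALSE)
    for (nm in names(hists)) {
      utils::write.csv(hists[[nm]],
                       file.path(dir, sprintf("hist_%s.csv", nm)),
                       row.names = FALSE, quote = FALSE)
    }
    prov <- list(
      package = "ca1sep",
      version = as.character(utils::packageVersion("ca1sep")),
      config = unclass(cfg),
      calibrations = lapply(result$calibrations, unclass),
      activity_at_target = result$activity_at_target
    )
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Write all artifacts of an experiment to a directory
#'
#' Serializes the complete run in plain text: the configuration
#' (`config.json`), connectivity edge lists with JSON sidecars, the
#' surrogate state, per-pathway sweep CSVs, and per condition the input and
#' output pattern files with a pair manifest and summary; finishes with the
#' [report()] outputs. Two runs from identical configurations produce
#' byte-identical artifact trees.
#'
#' @param result A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "ca1_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(result$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (pw in names(result$maps)) {
    write_projection(result$maps[[pw]],
                     file.path(dir, sprintf("connectivity_%s.tsv", pw)))
  }
  write_response_model(result$model, file.path(dir, "model.json"))
  for (pw in names(result$sweeps)) {
    write_sweep(result$sweeps[[pw]], file.path(dir, sprintf("sweep_%s.csv", pw)))
  }
  for (nm in names(result$conditions)) {
    cc <- result$conditions[[nm]]
    fa <- sprintf("inputs_%s_a.txt", nm)
    fb <- sprintf("inputs_%s_b.txt", nm)
    write_patterns(lapply(cc$pairs, `[[`, "a"), file.path(dir, fa))
    write_patterns(lapply(cc$pairs, `[[`, "b"), file.path(dir, fb))
    write_patterns(lapply(cc$outputs, `[[`, "a"),
                   file.path(dir, sprintf("outputs_%s_a.txt", nm)))
    write_patterns(lapply(cc$outputs, `[[`, "b"),
                   file.path(dir, sprintf("outputs_%s_b.txt", nm)))
    write_pair_manifest(cc$pairs, fa, fb, cc$pair_seeds,
                        file.path(dir, sprintf("manifest_%s.csv", nm)))
  }
  report(result, dir = file.path(dir, "report"))
  invisible(dir)
}

#' @export
print.ca1_experiment <- function(x, ...) {
  cat(sprintf("<ca1_experiment> %s scale: %d CA1 cells, %d pairs/condition\n",
              x$config$scale, x$config$n_post,
              x$config$n_pairs_per_condition))
  for (pw in names(x$calibrations)) {
    cal <- x$calibrations[[pw]]
    cat(sprintf("  %s: theta = %.4g, achieved spiking fraction %.4f (target %.2f)\n",
                pw, cal$theta, cal$achieved, cal$p_target))
  }
  print(report(x)$table, digits = 4)
  invisible(x)
}

#' @export
summary.ca1_experiment <- function(object, ...) {
  out <- report(object)
  out$calibrations <- object$calibrations
  out$activity_at_target <- object$activity_at_target
  out$analytic <- object$analytic
  class(out) <- "summary.ca1_experiment"
  out
}

#' @export
print.summary.ca1_experiment <- function(x, ...) {
  cat("Four-condition pattern-separation experiment\n\n")
  print(x$table, digits = 4)
  cat("\nCalibration:\n")
  for (pw in names(x$calibrations)) print(x$calibrations[[pw]])
  invisible(x)
}

#' Histograms of output Hamming distances per condition
#'
#' One panel per condition: the empirical histogram of pairwise output
#' Hamming distances with the chance-level normal approximation (analytic
#' mean and SD at the target spiking probability) overlaid.
#'
#' @param x A [run_experiment()] result.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.ca1_experiment <- function(x, ...) {
  nm <- names(x$conditions)
  old <- graphics::par(mfrow = c(length(nm) %/% 2 + length(nm) %% 2, 2))
  on.exit(graphics::par(old))
  for (n in nm) {
    cc <- x$conditions[[n]]
    s <- cc$hd_summary
    lim <- range(c(s$hds, s$stats$mean_hd + c(-4, 4) * s$stats$sd_hd))
    graphics::hist(s$hds, freq = FALSE, main = n, xlab = "output HD",
                   xlim = lim, ...)
    xs <- seq(lim[1], lim[2], length.out = 200)
    graphics::lines(xs, normal_approx_pdf(s$stats)(xs), col = "gray40")
  }
  invisible(x)
}
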
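test_that("desk configuration is self-consistent and mirrors the circuit ratios", {
  cfg <- make_desk_config(1)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$n_post, 500L)
  # CA3-like fan-out exceeds EC-like fan-out, as at full scale
  expect_identical(cfg$pathways$CA3$fanout, 75L)
  expect_identical(cfg$pathways$EC$fanout, 20L)
  expect_gt(cfg$pathways$CA3$fanout, cfg$pathways$EC$fanout)
  expect_gt(cfg$pathways$CA3$synapses_per_post,
            cfg$pathways$EC$synapses_per_post)
  # presyn_count round-trips with fanout_of on the generated spec
  for (pw in names(cfg$pathways)) {
    p <- cfg$pathways[[pw]]
    expect_identical(presyn_count(cfg$n_post, p$synapses_per_post, p$fanout),
                     p$n_pre)
    expect_identical(fanout_of(cfg$n_post, p$synapses_per_post, p$n_pre),
                     p$fanout)
    expect_true(p$activity > 0.05 && p$activity < 0.07)
  }
})

test_that("config validation rejects infeasible setups before any compute", {
  expect_error(
    experiment_config(100, list(CA3 = list(n_pre = 50, synapses_per_post = 60,
                                           fanout = 120, activity = 0.1))),
    "more synapse slots")
  expect_error(
    experiment_config(100, list(CA3 = list(n_pre = 200, synapses_per_post = 20,
                                           fanout = 3, activity = 0.1))),
    "fanout inconsistent")
  expect_error(
    experiment_config(100, list(CA3 = list(n_pre = 200, synapses_per_post = 20,
                                           fanout = 10, activity = 1e-4))),
    "infeasible active count")
  expect_error(make_desk_config(1, n_pairs_per_condition = 0),
               "at least one pair")
})

test_that("the full-scale preset is analytic-only", {
  cfg <- make_full_scale_config()
  expect_identical(cfg$scale, "full")
  expect_identical(cfg$pathways$CA3$n_pre, 28009L)
  expect_identical(cfg$pathways$EC$n_pre, 45073L)
  expect_error(run_experiment(cfg), "analytic-only")
  ref <- analytic_reference(cfg)
  expect_identical(ref$output$spiking_cells, 3290L)
  expect_identical(ref$pathways$similar_hd[ref$pathways$pathway == "CA3"],
                   62L)
  expect_identical(ref$pathways$similar_hd[ref$pathways$pathway == "EC"],
                   124L)
  expect_identical(ref$pathways$distinct_hd[ref$pathways$pathway == "CA3"],
                   2910L)
  expect_identical(ref$pathways$distinct_hd[ref$pathways$pathway == "EC"],
                   5750L)
})

test_that("run_experiment is deterministic end to end, artifacts included", {
  cfg <- quick_config(seed = 5, n_pairs = 4)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(report(r1)$table, report(r2)$table)
  expect_identical(r1$conditions$CA3.distinct$outputs,
                   r2$conditions$CA3.distinct$outputs)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment(r1, d1)
  write_experiment(r2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # a different master seed changes the outputs
  r3 <- run_experiment(quick_config(seed = 6, n_pairs = 4))
  expect_false(identical(report(r1)$table$mean_hd, report(r3)$table$mean_hd))
})

test_that("realized input distances equal their targets in every condition", {
  res <- run_experiment(quick_config(seed = 2, n_pairs = 5))
  for (cc in res$conditions) {
    for (pr in cc$pairs) {
      expect_identical(hamming(pr$a, pr$b), cc$input_hd)
      expect_identical(pr$a$k, cc$input_k)
      expect_identical(pr$b$k, cc$input_k)
    }
    for (o in cc$outputs) {
      expect_identical(o$a$length, res$config$n_post)
    }
  }
})

test_that("calibration transfers: output spiking fraction near target in all conditions", {
  res <- run_experiment(quick_config(seed = 3, n_pairs = 8))
  for (cc in res$conditions) {
    frac <- mean(cc$output_counts) / res$config$n_post
    expect_lt(abs(frac - res$config$p_target), 0.02)
  }
})

test_that("separation structure: similar < distinct, distinct at chance", {
  res <- run_experiment(quick_config(seed = 4, n_pairs = 10))
  tab <- report(res)$table
  for (pw in c("CA3", "EC")) {
    sim <- tab$mean_hd[tab$pathway == pw & tab$condition == "similar"]
    dis <- tab$mean_hd[tab$pathway == pw & tab$condition == "distinct"]
    expect_lt(sim, dis)
    se <- tab$analytic_sd[tab$pathway == pw & tab$condition == "distinct"] /
      sqrt(tab$n_pairs[tab$pathway == pw & tab$condition == "distinct"])
    expect_lt(abs(dis - tab$analytic_mean[tab$pathway == pw &
                                            tab$condition == "distinct"]),
              4 * se)
  }
})

test_that("report demands a complete result and returns the full table", {
  res <- run_experiment(quick_config(seed = 7, n_pairs = 4))
  out <- report(res)
  expect_identical(nrow(out$table), 4L)
  expect_true(all(c("pathway", "condition", "n_pairs", "input_hd", "mean_hd",
                    "sd_hd", "analytic_mean", "analytic_sd",
                    "separation_ratio") %in% names(out$table)))
  expect_length(out$histograms, 4)
  partial <- res
  partial$conditions$EC.similar <- NULL
  expect_error(report(partial), "incomplete")
  # provenance JSON round-trips
  d <- withr::local_tempdir()
  report(res, dir = d)
  prov <- jsonlite::read_json(file.path(d, "provenance.json"),
                              simplifyVector = TRUE)
  expect_identical(prov$config$seeds$patterns, res$config$seeds$patterns)
  expect_equal(prov$calibrations$CA3$theta, res$calibrations$CA3$theta)
})

test_that("sweep and Boltzmann fit are populated when enabled", {
  cfg <- make_desk_config(9, n_pairs_per_condition = 3,
                          sweep_patterns = 40, calib_patterns = 30)
  res <- run_experiment(cfg)
  expect_s3_class(res$sweeps$CA3, "activity_sweep")
  expect_s3_class(res$fits$CA3, "boltzmann_fit")
  # the inverted activity for the target probability is close to the nominal
  # calibrated operating point
  for (pw in c("CA3", "EC")) {
    act <- res$activity_at_target[[pw]]
    expect_true(is.finite(act))
    expect_lt(abs(act - cfg$pathways[[pw]]$activity) /
                cfg$pathways[[pw]]$activity, 0.35)
  }
})

test_that("published full-scale reference values are available for comparison", {
  ref <- reference_output_hd()
  expect_identical(dim(ref), c(4L, 6L))
  # qualitative structure mirrored by the surrogate: similar < distinct
  for (pw in c("CA3", "EC")) {
    expect_lt(ref$mean_hd[ref$pathway == pw & ref$condition == "similar"],
              ref$mean_hd[ref$pathway == pw & ref$condition == "distinct"])
  }
})
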
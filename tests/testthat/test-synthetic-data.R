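test_that("clonality calibration hits its target at cohort scale", {
  sim <- simulate_repertoire(simulation_config(
    n_clones = 30000, depth = 1000000, clonality_target = 0.24,
    n_true_groups = 0, seed = 1))
  s <- repertoire_summary(sim$repertoire)
  expect_lt(abs(s$clonality - 0.24), 0.01)
  expect_equal(s$n_clones, 30000L)
  expect_equal(s$total_reads, 1e6)
})

test_that("nothing planted and no errors means zero convergence, exactly", {
  sim <- simulate_repertoire(simulation_config(
    n_clones = 500, depth = 25000, clonality_target = 0.15,
    n_true_groups = 0, seed = 2))
  expect_identical(convergence(sim$repertoire)$statistic, 0)
  expect_identical(sim$truth$true_convergence, 0)
})

test_that("planted aggregate frequency is recovered by the metrics module", {
  for (seed in 1:20) {
    cfg <- simulation_config(
      n_clones = 400, depth = 20000,
      clonality_target = runif(1, 0.05, 0.3),
      convergence_target = runif(1, 0.005, 0.06), seed = seed)
    sim <- simulate_repertoire(cfg)
    expect_equal(convergence(sim$repertoire)$statistic,
                 sim$truth$true_convergence, tolerance = 1e-12)
    tg <- sim$truth$planted_groups
    expect_true(all(tg$size >= 2))
    expect_true(all(!duplicated(unlist(tg$members))))
  }
})

test_that("simulation is a pure function of config and seed", {
  cfg <- simulation_config(n_clones = 300, depth = 15000,
                           clonality_target = 0.2, n_true_groups = 5,
                           seed = 77)
  a <- simulate_repertoire(cfg)
  b <- simulate_repertoire(cfg)
  expect_identical(a$repertoire$clones, b$repertoire$clones)
  expect_identical(a$truth$planted_groups, b$truth$planted_groups)
})

test_that("read subsampling is multinomial, deterministic, and consistent in the limit", {
  sim <- simulate_repertoire(simulation_config(
    n_clones = 100, depth = 100000, clonality_target = 0.2,
    n_true_groups = 0, seed = 5))
  one <- sample_reads(sim$repertoire, 1, seed = 3)
  expect_equal(nrow(one$clones), 1L)
  expect_equal(one$total_reads, 1)
  a <- sample_reads(sim$repertoire, 5000, seed = 9)
  b <- sample_reads(sim$repertoire, 5000, seed = 9)
  expect_identical(a$clones, b$clones)
  deep <- sample_reads(sim$repertoire, 5e6, seed = 11)
  merged <- merge(sim$repertoire$clones[, c("cdr3_nt", "frequency")],
                  deep$clones[, c("cdr3_nt", "frequency")], by = "cdr3_nt")
  expect_lt(max(abs(merged$frequency.x - merged$frequency.y)), 0.002)
})

test_that("error injection at rate zero is a no-op with an empty artifact list", {
  sim <- simulate_repertoire(simulation_config(
    n_clones = 200, depth = 10000, clonality_target = 0.2,
    n_true_groups = 3, seed = 6))
  out <- inject_errors(sim$repertoire, 0, seed = 1)
  expect_identical(out$repertoire$clones, sim$repertoire$clones)
  expect_equal(nrow(out$truth$artifact_clones), 0L)
})

test_that("monoclonal error injection matches the binomial error expectation", {
  aa <- "CASSLGQAYEQYF"  # 13 aa -> 33-base window
  mono <- tcr_repertoire(data.frame(
    cdr3_nt = back_translate_test(aa), cdr3_aa = aa, v_call = "TRBV9",
    read_count = 1000000, productive = TRUE))
  e <- 1e-3
  out <- inject_errors(mono, e, seed = 8)
  w <- 3 * (nchar(aa) - 2)
  p_err <- 1 - (1 - e)^w
  expected <- 1e6 * p_err
  errored <- sum(out$truth$artifact_clones$reads) + out$truth$dropped_reads
  expect_lt(abs(errored - expected), 3 * sqrt(1e6 * p_err * (1 - p_err)))
  expect_gt(convergence(out$repertoire)$statistic, 0)
  # read conservation up to stop-codon drops
  expect_equal(out$repertoire$total_reads + out$truth$dropped_reads, 1e6)
  # artifacts all carry the parent V gene
  expect_true(all(out$truth$artifact_clones$v_gene == "TRBV9"))
})

test_that("realised convergence rises with the injected error rate", {
  rates <- c(1e-5, 1e-4, 1e-3, 1e-2)
  means <- vapply(rates, function(e) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_repertoire(simulation_config(
        n_clones = 400, depth = 60000, clonality_target = 0.2,
        n_true_groups = 0, error_rate = e, seed = 900 + s))
      sim$truth$realized_convergence_with_errors
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohort generation is calibrated, labelled, deterministic, and writable", {
  out_dir <- withr::local_tempdir()
  co <- generate_cohort(11, 11, seed = 5, n_clones = 400, depth = 20000,
                        out_dir = out_dir)
  expect_equal(nrow(co$features), 22L)
  expect_equal(sum(co$features$response == "responder"), 11L)
  expect_length(list.files(out_dir, pattern = "subject.*\\.tsv"), 22L)
  expect_true(file.exists(file.path(out_dir, "features.tsv")))
  back <- read_clonotype_table(file.path(out_dir, "subject01.tsv"),
                               "immunoseq")
  expect_equal(back$total_reads, co$repertoires[[1]]$total_reads)
  co2 <- generate_cohort(11, 11, seed = 5, n_clones = 400, depth = 20000)
  expect_identical(co$features, co2$features)
  # class-conditional medians near their calibration targets
  big <- generate_cohort(50, 50, seed = 31, n_clones = 400, depth = 25000)
  med_r <- median(big$features$convergence[big$features$response ==
                                             "responder"])
  med_n <- median(big$features$convergence[big$features$response !=
                                             "responder"])
  expect_lt(abs(med_r - 0.022) / 0.022, 0.5)
  expect_lt(abs(med_n - 0.008) / 0.008, 0.5)
  expect_gt(median(big$features$clonality[big$features$response ==
                                            "responder"]),
            median(big$features$clonality[big$features$response !=
                                            "responder"]))
})
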
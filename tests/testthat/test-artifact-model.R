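test_that("synonymous substitution probability matches exhaustive enumeration", {
  # independent oracle: enumerate all 61 x 9 substitutions via Biostrings
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  syn <- 0L
  for (codon in sense) {
    for (pos in 1:3) {
      for (b in bases) {
        if (substring(codon, pos, pos) == b) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (gc[[mut]] == gc[[codon]]) syn <- syn + 1L
      }
    }
  }
  expect_equal(synonymous_substitution_prob(), syn / (61 * 9))
  # methionine's codon has no synonymous single-base neighbour
  atg_syn <- sum(vapply(1:3, function(pos) {
    sum(vapply(setdiff(bases, substring("ATG", pos, pos)), function(b) {
      mut <- "ATG"; substr(mut, pos, pos) <- b
      gc[[mut]] == "M"
    }, logical(1)))
  }, numeric(1)))
  expect_equal(atg_syn, 0)
  # amino-acid-uniform weighting down-weights degenerate codons
  expect_lt(synonymous_substitution_prob("amino_acid"),
            synonymous_substitution_prob("codon"))
})

test_that("clone artifact probability has the closed binomial-complement form", {
  expect_equal(clone_artifact_probability(100, 10, error_model_config(0)), 0)
  # q = 0.4 * 0.25 = 0.1, one read of one effective residue: 1 - 0.9^3
  cfg <- error_model_config(0.4, synonymous_prob = 0.25)
  expect_equal(clone_artifact_probability(1, 1, cfg), 1 - 0.9^3)
  # monotone in reads, length, and rate
  cfg2 <- error_model_config(1e-3)
  p_reads <- clone_artifact_probability(c(1, 10, 100, 1000), 11, cfg2)
  expect_true(all(diff(p_reads) > 0))
  p_len <- clone_artifact_probability(50, c(2, 6, 12, 18), cfg2)
  expect_true(all(diff(p_len) > 0))
  p_rate <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(e)
    clone_artifact_probability(50, 11, error_model_config(e)), numeric(1))
  expect_true(all(diff(p_rate) > 0))
  expect_true(all(p_reads >= 0 & p_reads <= 1))
})

test_that("artifact probability matches a read-level Monte-Carlo oracle", {
  # MC over actual sequences: substitute each window base with prob e and
  # an actual uniformly chosen alternative base; flag if any errored read
  # is CDR3-synonymous. Uses the sequence's own enumerated synonymous
  # fraction as synonymous_prob, so the closed form and the oracle describe
  # the same experiment.
  set.seed(202)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  for (case in list(list(r = 20, aa = "CASSLGQAYEQYF", e = 2e-3),
                    list(r = 60, aa = "CASSLDRGF", e = 1.5e-3))) {
    nt <- back_translate_test(case$aa)
    win <- substr(nt, 4, nchar(nt) - 3)
    w <- nchar(win)
    # per-base synonymous fraction of this window, by enumeration
    syn_by_pos <- matrix(FALSE, w, 3)
    for (p in seq_len(w)) {
      codon_i <- (p - 1) %/% 3
      codon <- substr(win, codon_i * 3 + 1, codon_i * 3 + 3)
      alts <- setdiff(bases, substring(win, p, p))
      for (a in seq_along(alts)) {
        mut <- codon
        substr(mut, (p - 1) %% 3 + 1, (p - 1) %% 3 + 1) <- alts[a]
        syn_by_pos[p, a] <- gc[[mut]] == gc[[codon]]
      }
    }
    s_seq <- mean(syn_by_pos)
    model <- clone_artifact_probability(
      case$r, nchar(case$aa) - 2,
      error_model_config(case$e, synonymous_prob = s_seq))
    n_rep <- 4000
    flagged <- logical(n_rep)
    for (k in seq_len(n_rep)) {
      n_err <- rbinom(1, case$r * w, case$e)
      if (n_err == 0) next
      pos <- sample.int(w, n_err, replace = TRUE)
      alt <- sample.int(3, n_err, replace = TRUE)
      flagged[k] <- any(syn_by_pos[cbind(pos, alt)])
    }
    se <- sqrt(model * (1 - model) / n_rep)
    expect_lt(abs(mean(flagged) - model), 3 * se + 1e-3)
  }
})

test_that("artifact read thresholds use the binomial tail", {
  cfg <- error_model_config(0.01, synonymous_prob = 0.25,
                            artifact_read_threshold = 2)
  q <- 0.01 * 0.25
  B <- 10 * 3 * 4
  direct <- 1 - (1 - q)^B - B * q * (1 - q)^(B - 1)
  expect_equal(clone_artifact_probability(10, 4, cfg), direct,
               tolerance = 1e-10)
})

test_that("predicted convergence behaves at its limits", {
  sim <- simulate_repertoire(simulation_config(
    n_clones = 200, depth = 10000, clonality_target = 0.2,
    n_true_groups = 0, seed = 9))
  expect_equal(predicted_convergence(sim$repertoire, error_model_config(0)), 0)
  # monoclonal at depth: saturates toward 1
  aa <- c("CASSLGQAYEQYF", "CAWSVGQF")
  mono <- tcr_repertoire(data.frame(
    cdr3_nt = back_translate_test(aa), cdr3_aa = aa,
    v_call = c("TRBV1", "TRBV2"), read_count = c(999999, 1),
    productive = TRUE))
  expect_gt(predicted_convergence(mono, error_model_config(1e-2)), 0.99)
  # monotone in the error rate
  grid <- error_rate_grid()
  preds <- vapply(grid, function(e)
    predicted_convergence(sim$repertoire, error_model_config(e)), numeric(1))
  expect_true(all(diff(preds) >= 0))
  # and in depth under proportional read scaling
  cl <- sim$repertoire$clones
  cl$read_count <- cl$read_count * 10
  deeper <- tcr_repertoire(cl)
  expect_gte(predicted_convergence(deeper, error_model_config(1e-3)),
             predicted_convergence(sim$repertoire, error_model_config(1e-3)))
})

test_that("grid fit fails informatively on constant observed convergence", {
  reps <- lapply(1:6, function(s) random_repertoire(40, s))
  expect_error(fit_error_rate(reps, rep(0.05, 6)), "undefined")
})

test_that("the default grid is log-spaced at 13 points per decade", {
  g <- error_rate_grid()
  expect_equal(g[1], 1e-5)
  expect_equal(g[length(g)], 1e-2)
  expect_equal(length(g), 37L)
  expect_equal(diff(log10(g)), rep(1 / 12, 36), tolerance = 1e-12)
})

test_that("grid fit localises an injected error rate on a small cohort", {
  # a 12-sample, 600-clone cohort is a smoke test: rank resolution at this
  # size is coarse, so the bound is loose; the full-size recovery runs in
  # the end-to-end suite
  cohort <- error_recovery_cohort(1e-3, seed = 4, n_samples = 12,
                                  n_clones = 600)
  fit <- fit_error_rate(
    cohort$repertoires, cohort$observed,
    synonymous_prob = synonymous_substitution_prob("amino_acid"))
  expect_lte(fit$best_rate, 4e-3)
  expect_gte(fit$best_rate, 2.5e-4)
  expect_gt(fit$best_correlation, 0.7)
  expect_true(fit$best_rate %in% fit$grid)
  expect_equal(fit$best_correlation,
               max(fit$correlation_per_rate, na.rm = TRUE))
})
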
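test_that("identical scenario specs give bit-identical trial tables", {
  spec <- packaged_scenarios(seed = 9)$animal
  expect_identical(generate_srt_data(spec), generate_srt_data(spec))
  other <- packaged_scenarios(seed = 10)$animal
  expect_false(identical(generate_srt_data(spec), generate_srt_data(other)))
})

test_that("pure null scenario is 50/50 at every latency", {
  null_spec <- scenario_spec("null", task = "animal",
                             latency = list(shift = 80, mu = 59, sigma = 32,
                                            tau = 48),
                             selective_onset_ms = Inf,
                             selective_correct_prob = 0.5, seed = 21)
  trials <- generate_srt_data(null_spec)
  acc <- mean(trial_correct(trials))
  se <- sqrt(0.25 / nrow(trials))
  expect_lt(abs(acc - 0.5), 4 * se)
  expect_true(is.na(min_srt(bin_srt_distribution(trials))$onset_ms))

  # per-bin correct/error counts over replicates stay consistent with 50/50:
  # the per-bin chi-square p-values are uniform (aggregated over 40 seeds)
  pvals <- unlist(lapply(1:40, function(r) {
    s <- null_spec; s$seed <- 100L + r
    d <- bin_srt_distribution(generate_srt_data(s))
    keep <- d$bins$n_correct + d$bins$n_error >= 20
    chi2_correct_vs_error(d$bins$n_correct[keep], d$bins$n_error[keep])$p
  }))
  # jitter the discrete chi-square p-values below bin resolution to avoid
  # KS ties; the uniformity check is unaffected
  withr::with_seed(1, pvals <- pvals + runif(length(pvals), -1e-9, 1e-9))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("degenerate fully-selective scenario is at ceiling", {
  spec <- scenario_spec("ceiling", task = "animal",
                        latency = list(shift = 100, mu = 80, sigma = 20,
                                       tau = 30),
                        selective_onset_ms = 80,
                        selective_correct_prob = 1, seed = 3)
  expect_equal(mean(trial_correct(generate_srt_data(spec))), 1)
})

test_that("simulated accuracy matches the analytic mixture expectation", {
  # oracle: P(L < t_sel) p_ns + P(L >= t_sel) p_sel by numerical integration
  # of the truncated latency density (jitter integrated over a normal grid)
  spec <- packaged_scenarios()$animal
  nodes <- stats::qnorm((1:41 - 0.5) / 41) * spec$subject_mu_sd
  lat <- spec$latency
  oracle <- mean(vapply(nodes, function(j) {
    f <- function(x) dexgauss(x, lat$shift, lat$mu + j, lat$sigma, lat$tau)
    z <- stats::integrate(f, 80, 800)$value
    q <- stats::integrate(f, 80, spec$selective_onset_ms)$value / z
    q * spec$nonselective_correct_prob +
      (1 - q) * spec$selective_correct_prob
  }, numeric(1)))
  accs <- vapply(1:10, function(r) {
    s <- spec; s$seed <- 500L + r
    mean(trial_correct(generate_srt_data(s)))
  }, numeric(1))
  se <- sqrt(oracle * (1 - oracle) / (10 * spec$n_subjects *
                                        spec$trials_per_subject))
  expect_lt(abs(mean(accs) - oracle), 4 * se)
  expect_equal(scenario_expected_accuracy(spec), oracle, tolerance = 0.005)
})

test_that("spoiled trials are emitted and cleaned by the filter", {
  spec <- packaged_scenarios(seed = 4)$animal
  spec$spoil_fraction <- 0.1
  trials <- generate_srt_data(spec)
  out <- filter_trials(trials)
  expect_gt(sum(out$report$n_total) - sum(out$report$n_kept), 0)
  expect_equal(mean(out$report$pct_excluded), 10, tolerance = 0.35)
  expect_true(all(out$trials$srt_ms >= 80 & out$trials$srt_ms <= 800))
})

test_that("paired and random context assignment have the stated pair mix", {
  spec <- packaged_scenarios(seed = 8)$animal_congruency
  lab <- label_congruency(generate_srt_data(spec))
  expect_equal(sum(lab == "mixed"), 0)
  expect_equal(mean(lab == "congruent"), 0.5, tolerance = 0.05)
  spec$context_assignment <- "random"
  lab <- label_congruency(generate_srt_data(spec))
  expect_equal(mean(lab == "mixed"), 0.5, tolerance = 0.05)
  expect_equal(mean(lab == "congruent"), 0.25, tolerance = 0.04)
})

test_that("raising the selective onset never lowers the estimated minimal SRT", {
  base <- packaged_scenarios()$animal
  onsets <- vapply(c(120, 160, 200), function(t_sel) {
    s <- base
    s$selective_onset_ms <- t_sel
    stats::median(replicate_min_srt(s, 15, seed = t_sel), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("scenario files round-trip through YAML", {
  specs <- packaged_scenarios(seed = 6)[c("animal", "animal_congruency")]
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_file(specs, path)
  back <- read_scenario_file(path)
  expect_equal(back, specs)
  # and the regenerated data is identical
  expect_identical(generate_srt_data(back$animal),
                   generate_srt_data(specs$animal))
})
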
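test_that("binning is half-open on a 10-ms grid from 80 ms", {
  d <- bin_srt_distribution(make_trials(c(80, 89, 90)))
  expect_equal(d$bins$n_correct[d$bins$bin_lower == 80], 2)
  expect_equal(d$bins$n_correct[d$bins$bin_lower == 90], 1)
  expect_equal(sum(d$bins$n_correct) + sum(d$bins$n_error), d$n_total)

  # percentages over a larger simulated set sum to 100
  trials <- filter_trials(generate_srt_data(packaged_scenarios()$animal))$trials
  d <- bin_srt_distribution(trials)
  expect_equal(sum(100 * (d$bins$n_correct + d$bins$n_error) / d$n_total), 100)

  # hand-listed SRTs with known correctness match an exhaustive tally
  srt <- c(82, 85, 95, 101, 103, 107, 119, 120, 155, 158, 161, 799)
  correct <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE,
               FALSE, TRUE, TRUE)
  d <- bin_srt_distribution(make_trials(srt, correct))
  for (b in unique(floor((srt - 80) / 10) * 10 + 80)) {
    inbin <- srt >= b & srt < b + 10 | (b == 790 & srt == 800)
    expect_equal(d$bins$n_correct[d$bins$bin_lower == b], sum(correct & inbin))
    expect_equal(d$bins$n_error[d$bins$bin_lower == b], sum(!correct & inbin))
  }
})

test_that("unfiltered input is rejected by the binner", {
  expect_error(bin_srt_distribution(make_trials(c(75, 120))), "filter_trials")
  tr <- make_trials(c(120, 130))
  tr$response_side[1] <- "none"
  expect_error(bin_srt_distribution(tr), "filter_trials")
})

test_that("per-bin chi-square matches the closed form and stats::chisq.test", {
  r <- chi2_correct_vs_error(10, 10)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_false(r$significant)

  r <- chi2_correct_vs_error(20, 5)
  expect_equal(r$chi2, 9)
  expect_equal(r$p, stats::pchisq(9, 1, lower.tail = FALSE))
  expect_lt(abs(r$p - 0.0027), 3e-4)
  expect_true(r$significant)

  # direction requirement: errors outnumbering correct never flags
  r <- chi2_correct_vs_error(5, 20)
  expect_lt(r$p, 0.05)
  expect_false(r$significant)

  # sparse bins never flag
  expect_false(chi2_correct_vs_error(4, 0)$significant)
  expect_false(chi2_correct_vs_error(0, 0)$significant)
  expect_true(is.na(chi2_correct_vs_error(0, 0)$chi2))

  # cross-check against the generic Pearson test on a few random tables
  withr::with_seed(5, {
    for (i in 1:10) {
      n <- sample(5:200, 2)
      ours <- chi2_correct_vs_error(n[1], n[2])
      ref <- stats::chisq.test(n, p = c(0.5, 0.5), correct = FALSE)
      expect_equal(ours$chi2, unname(ref$statistic))
      expect_equal(ours$p, unname(ref$p.value))
    }
  })
})

test_that("minimal SRT needs five consecutive qualifying bins", {
  # equal counts everywhere: no onset
  d <- make_distribution(rep(8, 12), rep(8, 12))
  expect_true(is.na(min_srt(d)$onset_ms))

  # (8,8) in [80,120), then (20,5) in each bin of [120,170): onset 120
  d <- make_distribution(c(rep(8, 4), rep(20, 5)), c(rep(8, 4), rep(5, 5)))
  expect_equal(min_srt(d)$onset_ms, 120)

  # a single significant bin followed by flat bins never fires at that bin
  d <- make_distribution(c(rep(8, 6), 20, rep(8, 5)),
                         c(rep(8, 6), 5, rep(8, 5)))
  res <- min_srt(d)
  expect_true(is.na(res$onset_ms))

  # four qualifying followers are not enough if the fifth breaks the run
  d <- make_distribution(c(rep(20, 4), 8, rep(20, 5)),
                         c(rep(5, 4), 8, rep(5, 5)))
  expect_equal(min_srt(d)$onset_ms, 130)
})

test_that("minimal SRT is translation-equivariant on the bin grid", {
  spec <- packaged_scenarios(seed = 31)$animal
  trials <- filter_trials(generate_srt_data(spec))$trials
  onset <- min_srt(bin_srt_distribution(trials))$onset_ms
  shifted <- trials
  shifted$srt_ms <- pmin(shifted$srt_ms + 10, 800)
  onset_shift <- min_srt(bin_srt_distribution(shifted))$onset_ms
  expect_equal(onset_shift, onset + 10)
})

test_that("group summary handles constant and two-subject data exactly", {
  gs <- group_summary(make_trials(rep(200, 20)), n_resamples = 200)
  expect_equal(gs$accuracy$estimate, 100)
  expect_equal(gs$median_srt$estimate, 200)
  expect_equal(c(gs$median_srt$lower, gs$median_srt$upper), c(200, 200))

  two <- dplyr::bind_rows(make_trials(c(170, 180, 190), subject = "S01"),
                          make_trials(c(180, 190, 200), subject = "S02"))
  gs <- group_summary(two, n_resamples = 200)
  expect_equal(gs$median_srt$estimate, mean(c(180, 190)))

  # a subject with no correct trial drops out of the latency mean
  mixed <- dplyr::bind_rows(make_trials(c(170, 180), subject = "S01"),
                            make_trials(c(300, 310), correct = FALSE,
                                        subject = "S02"))
  expect_warning(gs <- group_summary(mixed, n_resamples = 50),
                 "without correct trials")
  expect_equal(gs$median_srt$estimate, 175)
})

test_that("bootstrap CI of the median behaves on constant and sane data", {
  ci <- bootstrap_median_ci(rep(5, 50), n_resamples = 100)
  expect_equal(c(ci$lower, ci$upper), c(5, 5))
  withr::with_seed(2, {
    x <- rexgauss(200, 100, 50, 30, 70)
    ci <- bootstrap_median_ci(x, n_resamples = 500)
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
    expect_equal(ci$estimate, stats::median(x))
  })
})

test_that("permutation test agrees with the exhaustive-enumeration oracle", {
  # identical samples: no effect
  withr::with_seed(1, {
    r <- permutation_test(c(1, 2, 3), c(1, 2, 3), n_permutations = 500)
    expect_gt(r$p_value, 0.5)
  })

  # oracle: enumerate every reassignment of the pooled values
  exhaustive_p <- function(a, b) {
    pooled <- c(a, b)
    obs <- mean(a) - mean(b)
    splits <- utils::combn(length(pooled), length(a))
    diffs <- apply(splits, 2, function(ix)
      mean(pooled[ix]) - mean(pooled[-ix]))
    mean(abs(diffs) >= abs(obs) - 1e-12)
  }
  expect_equal(exhaustive_p(c(1, 2), c(3, 4)), 2 / 6)

  withr::with_seed(17, {
    cases <- list(list(a = c(1, 2), b = c(3, 4)),
                  list(a = c(5, 1, 4), b = c(2, 2, 3)),
                  list(a = rnorm(5), b = rnorm(5) + 1),
                  list(a = runif(4), b = runif(6)))
    for (cs in cases) {
      exact <- exhaustive_p(cs$a, cs$b)
      mc <- permutation_test(cs$a, cs$b, n_permutations = 2000)
      se <- sqrt(exact * (1 - exact) / 2000)
      expect_lt(abs(mc$p_value - exact), 2 * se + 1 / 2001)
    }
  })

  expect_error(permutation_test(1, c(2, 3)), "at least 2")
})

test_that("permutation p has the Monte-Carlo floor, never zero", {
  withr::with_seed(3, {
    r <- permutation_test(1:12, 100 + 1:12, n_permutations = 2000)
    expect_equal(r$p_value, 1 / 2001)
    expect_equal(r$exceedance_count, 0)
    expect_output(print(r), "floor")
  })
})
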
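small_cfg <- function(...) generator_config(n_spots = 60, seed = 5, ...)

test_that("generation is deterministic: same config and seed, same bytes", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_study(small_cfg(), dir = d1)
  s2 <- generate_study(small_cfg(), dir = d2)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  for (k in seq_along(s1$files))
    expect_identical(readLines(s1$files[k]), readLines(s2$files[k]))
  # a different seed changes the data
  s3 <- generate_study(generator_config(n_spots = 60, seed = 6))
  expect_false(identical(s1$records$volume, s3$records$volume))
})

test_that("adding spots leaves earlier spots' draws untouched", {
  a <- generate_study(generator_config(n_spots = 30, seed = 5))
  b <- generate_study(generator_config(n_spots = 40, seed = 5))
  ids <- unique(a$records$spot_id)
  expect_identical(a$records$volume,
                   b$records$volume[b$records$spot_id %in% ids])
})

test_that("detection limits shape which profiles carry a spot", {
  sim <- generate_study(small_cfg())
  tr <- sim$truth[sim$truth$pattern_truth != "novel", ]
  rec <- sim$records
  for (i in seq_len(nrow(tr))) {
    id <- tr$spot_id[i]
    phos_mass <- tr$abundance_ng[i] * tr$phospho_frac[i]
    has_p <- any(rec$spot_id == id & rec$profile == "phospho")
    expect_equal(has_p, phos_mass >= 4)       # phosphostain limit 4 ng
    expect_true(any(rec$spot_id == id & rec$profile == "reference"))
  }
  # novel partners live only in the dephosphorylated profile
  nov <- sim$truth$spot_id[sim$truth$pattern_truth == "novel"]
  expect_true(length(nov) > 0)
  expect_true(all(rec$profile[rec$spot_id %in% nov] == "dephospho"))
})

test_that("ground-truth patterns match what the emitted volumes imply", {
  sim <- generate_study(small_cfg())
  rec <- sim$records; tr <- sim$truth
  for (i in which(tr$pattern_truth == "disappeared")) {
    expect_false(any(rec$spot_id == tr$spot_id[i] &
                     rec$profile == "dephospho"))
  }
  for (i in which(tr$pattern_truth == "unchanged")) {
    expect_equal(tr$phospho_frac[i], 0)
  }
})

test_that("the expected rate is 100 x the generating phospho-fraction", {
  sim <- generate_study(small_cfg())
  tr <- sim$truth
  expect_equal(expected_pr(tr, tr$spot_id), 100 * tr$phospho_frac)
  expect_error(expected_pr(tr, "bogus"), "unknown spot")
})

test_that("phosphostain detects fewer spots than dephosphorylation", {
  sim <- generate_study(generator_config(seed = 1))
  m <- match_profiles(normalize_study(sim$records), sim$design)
  fit <- phospho_rates(m, n_boot = 200, seed = 1)
  det <- summarize_detection(fit)
  expect_lt(det$n_proq_positive, det$n_hfp_positive)
})

test_that("the dephosphorylation rate tracks the true phospho-fraction", {
  sim <- generate_study(generator_config(noise_sigma = 0.05, seed = 1))
  m <- match_profiles(normalize_study(sim$records), sim$design)
  fit <- phospho_rates(m, n_boot = 100, seed = 1)
  h <- fit$results[fit$results$method == "hfp", ]
  i <- match(h$spot_id, sim$truth$spot_id)
  det <- !is.na(h$mean_pr) & !is.na(sim$truth$phospho_frac[i])
  err <- h$mean_pr[det] - 100 * sim$truth$phospho_frac[i][det]
  expect_gt(sum(det), 100)
  expect_gte(mean(abs(err) <= 5), 0.85)
  expect_lte(median(abs(err)), 2.5)
})

test_that("unadjusted interval coverage of the truth is reported sanely", {
  # N = 3 bootstrap intervals undercover; the rate is only sanity-bounded
  hits <- 0; n <- 0
  for (s in 1:3) {
    sim <- generate_study(generator_config(n_spots = 40, noise_sigma = 0.05,
                                           seed = s))
    m <- match_profiles(normalize_study(sim$records), sim$design)
    fit <- phospho_rates(m, n_boot = 400, seed = s, bonferroni_m = 1)
    h <- fit$results[fit$results$method == "hfp", ]
    i <- match(h$spot_id, sim$truth$spot_id)
    tru <- 100 * sim$truth$phospho_frac[i]
    ok <- !is.na(h$mean_pr) & !is.na(tru) & h$se_pr > 0
    hits <- hits + sum(h$ci_low[ok] <= tru[ok] & tru[ok] <= h$ci_high[ok])
    n <- n + sum(ok)
  }
  expect_gt(n, 50)
  expect_gt(hits / n, 0.3)
  expect_lte(hits / n, 1)
})

test_that("generator rejects inconsistent configurations", {
  expect_error(generator_config(n_spots = 0))
  expect_error(generator_config(frac_nonphospho = 0.7,
                                frac_full_phospho = 0.4))
  expect_error(generator_config(noise_sigma = -0.1))
})
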
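test_that("phosphostain rate follows P/T with the clamp and absence rules", {
  expect_equal(pr_proq(50, 100), 50)
  expect_equal(pr_proq(120, 100), 100)   # saturated: clamp to 100
  expect_equal(pr_proq(NA, 100), 0)      # no phosphostain signal
  expect_error(pr_proq(10, 0), "T must be > 0")
  expect_error(pr_proq(10, NA), "T must be > 0")
  # non-decreasing in P
  ps <- seq(0, 150, by = 5)
  expect_true(all(diff(vapply(ps, pr_proq, 0, T_ = 100)) >= 0))
})

test_that("dephosphorylation rate follows (T-D)/T with the N/A rule", {
  expect_equal(pr_hfp(100, 25), 75)
  expect_equal(pr_hfp(100, NA), 100)     # spot disappeared
  expect_true(is.na(pr_hfp(100, 120)))   # more volume after treatment
  expect_error(pr_hfp(0, 10), "T must be > 0")
  # strictly decreasing in D on (0, T]
  ds <- seq(1, 100, by = 1)
  expect_true(all(diff(vapply(ds, pr_hfp, 0, T_ = 100)) < 0))
})

test_that("degenerate replicate vectors give point-mass intervals", {
  for (c0 in c(100, 0, 42.5)) {
    ci <- bootstrap_ci_bc(rep(c0, 3), n_boot = 2000, seed = 1)
    expect_equal(as.vector(ci), c(c0, c0))
  }
  expect_true(all(is.na(bootstrap_ci_bc(c(NA, NA, NA)))))
  expect_warning(bootstrap_ci_bc(c(1, 2, 3), n_boot = 50, seed = 1),
                 "unstable")
})

test_that("Monte-Carlo BC interval matches the exact resample enumeration", {
  v <- c(40, 50, 60)
  exact <- exact_bc_ci(v, 0.95)
  mc <- bootstrap_ci_bc(v, n_boot = 1e5, conf_level = 0.95, seed = 4)
  expect_lt(max(abs(mc - exact)), 0.5)
  # endpoints always inside the support of the resample means
  set.seed(8)
  for (k in 1:20) {
    v <- runif(3, 0, 100)
    ci <- bootstrap_ci_bc(v, n_boot = 500, seed = k)
    expect_gte(ci[1], min(v)); expect_lte(ci[2], max(v))
    expect_lte(ci[1], ci[2])
  }
})

test_that("bootstrap draws are reproducible from the seed", {
  v <- c(10, 55, 70)
  expect_identical(bootstrap_ci_bc(v, 2000, seed = 99),
                   bootstrap_ci_bc(v, 2000, seed = 99))
})

test_that("Bonferroni level is alpha over the comparison count", {
  expect_equal(bonferroni_level(0.05, 1), 0.05)
  expect_equal(bonferroni_level(0.05, 174), 0.05 / 174)
  expect_equal(bonferroni_level(0.05, 5), 0.01)
  expect_error(bonferroni_level(1.2, 3), "alpha")
  expect_error(bonferroni_level(0.05, 0), "positive integer")
})

test_that("CI-overlap significance reproduces the published calls", {
  res <- function(lo, hi, mean = (lo + hi) / 2)
    list(spot_id = "s", mean_pr = mean, ci_low = lo, ci_high = hi)
  # disjoint intervals -> significant
  expect_equal(compare_methods_per_spot(res(56.5, 62.8), res(100, 100)),
               "significant")
  # overlapping -> ns
  expect_equal(compare_methods_per_spot(res(37.5, 89.9), res(34.0, 87.3)),
               "ns")
  # identical point masses -> ns
  expect_equal(compare_methods_per_spot(res(100, 100), res(100, 100)), "ns")
  # symmetric in method order
  expect_equal(compare_methods_per_spot(res(100, 100), res(56.5, 62.8)),
               "significant")
  na <- list(spot_id = "s", mean_pr = NA, ci_low = NA, ci_high = NA)
  expect_equal(compare_methods_per_spot(na, res(1, 2)), "not_comparable")
  bad <- res(1, 2); bad$spot_id <- "other"
  expect_error(compare_methods_per_spot(bad, res(1, 2)), "different spots")
})

test_that("Fisher exact p matches exhaustive enumeration and fisher.test", {
  expect_equal(fisher_exact_two_tailed(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_two_tailed(matrix(c(1, 0, 0, 1), 2,
                                              byrow = TRUE)), 1)
  big <- matrix(c(152, 22, 44, 130), 2, byrow = TRUE)
  expect_lt(fisher_exact_two_tailed(big), 1e-4)
  expect_equal(fisher_exact_two_tailed(big), fisher_enum(big),
               tolerance = 1e-12)
  set.seed(31)
  for (k in 1:150) {
    tab <- matrix(rpois(4, sample(0:9, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_two_tailed(tab)
    expect_equal(p, fisher_enum(tab), tolerance = 1e-10)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_warning(p0 <- fisher_exact_two_tailed(matrix(c(0, 0, 3, 4), 2,
                                                      byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact_two_tailed(matrix(c(1, 2, 3, -1), 2)),
               "non-negative")
})

test_that("the fitted object carries per-spot rates, CIs and calls", {
  # s1: disappeared (PR 100,100,100); s2: unphosphorylated (0,0,0);
  # s3: halves its volume; s4: D > T in one replicate -> spot-level N/A
  Tm <- const_mat(100, 4)
  Dm <- rbind(c(NA, NA, NA), c(100, 100, 100), c(50, 40, 60),
              c(90, 120, 80))
  Pm <- rbind(c(NA, NA, NA), c(NA, NA, NA), c(20, 25, 30), c(NA, NA, NA))
  fit <- phospho_rates(mk_matched(Tm, Pm, Dm), n_boot = 500, seed = 2)
  r <- fit$results
  h <- r[r$method == "hfp", ]; q <- r[r$method == "proq", ]

  expect_equal(h$mean_pr[1], 100); expect_equal(h$se_pr[1], 0)
  expect_equal(c(h$ci_low[1], h$ci_high[1]), c(100, 100))
  expect_equal(h$mean_pr[2], 0)
  expect_equal(c(h$ci_low[2], h$ci_high[2]), c(0, 0))
  expect_equal(h$mean_pr[3], 50)
  expect_true(is.na(h$mean_pr[4]))                 # N/A convention
  expect_equal(h$significant[4], "not_comparable")
  expect_equal(q$mean_pr[3], 25)
  expect_equal(q$mean_pr[2], 0)
  # all reported rates within [0, 100], intervals ordered
  ok <- !is.na(r$mean_pr)
  expect_true(all(r$mean_pr[ok] >= 0 & r$mean_pr[ok] <= 100))
  expect_true(all(r$ci_low[ok] <= r$ci_high[ok]))
})

test_that("phosphostain signal failing the detection rule counts as zero", {
  Tm <- const_mat(100, 1)
  Pm <- matrix(c(80, NA, NA), 1)   # detected in 1 of 3 replicates only
  Dm <- const_mat(60, 1)
  fit <- phospho_rates(mk_matched(Tm, Pm, Dm), n_boot = 200, seed = 1)
  q <- fit$results[fit$results$method == "proq", ]
  expect_equal(q$mean_pr, 0)
  expect_equal(unlist(q[paste0("pr_rep", 1:3)], use.names = FALSE),
               c(0, 0, 0))
})

test_that("a pre-matched spot recorded at a shifted position vacates its origin", {
  co <- data.frame(x_reference = 0.5, y_reference = 0.5,
                   x_dephospho = 0.55, y_dephospho = 0.5)
  fit <- phospho_rates(mk_matched(const_mat(100, 1), const_mat(NA_real_, 1),
                                  const_mat(95, 1), coords = co),
                       n_boot = 200, seed = 1)
  h <- fit$results[fit$results$method == "hfp", ]
  expect_equal(h$mean_pr, 100)   # volume left the original position
})

test_that("detection summary tallies methods and runs the exact test", {
  fit <- phospho_rates(detection_fixture(10, 0, 0), n_boot = 100, seed = 1)
  expect_warning(det <- summarize_detection(fit), "zero margin")
  expect_equal(det$pct_hfp, 0)
  expect_equal(det$pct_proq, 0)
  expect_true(is.na(det$fold_ratio))

  fit2 <- phospho_rates(detection_fixture(20, 15, 5), n_boot = 100, seed = 1)
  det2 <- summarize_detection(fit2)
  expect_equal(det2$n_hfp_positive, 15)
  expect_equal(det2$n_proq_positive, 5)
  expect_equal(det2$pct_hfp, 75.0)
  expect_equal(det2$fold_ratio, 3)
  expect_equal(unname(rowSums(det2$table)), c(20, 20))
  expect_equal(det2$fisher_p, fisher_enum(det2$table), tolerance = 1e-10)
})

test_that("the paired-difference bootstrap rule agrees on clear-cut spots", {
  # far apart: significant; identical: ns
  Tm <- const_mat(100, 2)
  Dm <- rbind(c(NA, NA, NA), c(52, 50, 48))
  Pm <- rbind(c(1, 2, 1), c(51, 50, 49))
  fit <- phospho_rates(mk_matched(Tm, Pm, Dm), n_boot = 1000, seed = 3,
                       significance_rule = "diff_bootstrap")
  h <- fit$results[fit$results$method == "hfp", ]
  expect_equal(h$significant[1], "significant")
  expect_equal(h$significant[2], "ns")
})
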
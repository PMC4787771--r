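test_that("profiles built from one stage load entirely on that stage", {
  d <- canonical_design()
  # exact condition indicator: all variance at the condition stage
  y <- as.numeric(d$condition == "G")
  expect_equal(nested_r2(y, d),
               c(condition = 1, biological = 0, preparation = 0,
                 residual = 0))
  # equal within preparation pairs, differing across preparations, no
  # condition/biological structure: residual 0, preparation dominant
  prep_vals <- setNames(c(0, 5, 1, 4, 2, 3, 2.5, 3.5),
                        unique(d$preparation))
  y2 <- prep_vals[d$preparation]
  fr2 <- nested_r2(y2, d)
  expect_equal(unname(fr2["residual"]), 0)
  expect_gt(fr2["preparation"], max(fr2["condition"], fr2["biological"]))
  # degenerate flat profile warns and returns NA
  expect_warning(fr3 <- nested_r2(rep(1, 16), d), "degenerate")
  expect_true(all(is.na(fr3)))
})

test_that("gaussian decomposition matches the brute-force ANOVA oracle on 100 random profiles", {
  d <- canonical_design()
  set.seed(100)
  for (i in 1:100) {
    y <- rnorm(16, sd = sample(c(0.2, 1, 5), 1))
    expect_lt(max(abs(nested_r2(y, d) - oracle_nested_gauss(y, d))), 1e-10)
  }
})

test_that("count decomposition matches the closed-form Poisson group-MLE oracle", {
  d <- canonical_design()
  # fixture: a hand-sized count profile
  y_fix <- c(12, 15, 9, 14, 30, 28, 25, 33, 7, 5, 8, 6, 18, 22, 16, 21)
  lib <- rep(1000, 16)
  expect_lt(max(abs(count_nested_r2(y_fix, d, lib) -
                      oracle_nested_count(y_fix, d, lib))), 1e-8)
  set.seed(101)
  for (i in 1:100) {
    lib <- runif(16, 5e4, 2e5)
    y <- rpois(16, exp(rnorm(1, 2.5, 1.5)) * lib / 1e5)
    if (sum(y) == 0) next
    expect_lt(max(abs(count_nested_r2(y, d, lib) -
                        oracle_nested_count(y, d, lib))), 1e-8)
  }
  # counts fit exactly by the preparation-level model: residual 0
  prep_means <- setNames(c(10, 40, 20, 80, 160, 320, 640, 1280),
                         unique(d$preparation))
  y3 <- as.numeric(prep_means[d$preparation])
  expect_equal(unname(count_nested_r2(y3, d, rep(1e5, 16))["residual"]), 0)
  # all group means equal: condition component ~ 0 after adjustment
  expect_warning(fr <- count_nested_r2(rep(0L, 16), d, rep(1, 16)),
                 "degenerate")
  expect_true(all(is.na(fr)))
  # all group means equal: condition component ~ 0 after adjustment
  y4 <- rep(c(24L, 26L), 8)
  expect_lt(count_nested_r2(y4, d, rep(1e5, 16))["condition"], 0.05)
  # exactly constant profiles carry no deviance information
  expect_warning(fr4 <- count_nested_r2(rep(25L, 16), d, rep(1e5, 16)),
                 "degenerate")
  expect_true(all(is.na(fr4)))
})

test_that("raw R-squared is monotone under model nesting and fractions are location/scale invariant", {
  d <- canonical_design()
  set.seed(102)
  for (i in 1:50) {
    y <- rnorm(16)
    r2 <- oracle_raw_r2(y, d)
    expect_true(all(diff(r2) >= -1e-12))
    expect_equal(nested_r2(3.2 - 1.7 * y, d), nested_r2(y, d),
                 tolerance = 1e-10)
  }
})

test_that("matrix decomposition reproduces per-gene results and propagates degeneracy as flags", {
  d <- canonical_design()
  set.seed(103)
  m <- matrix(rnorm(5 * 16), 5, 16,
              dimnames = list(paste0("g", 1:5), d$sample))
  m[3, ] <- m[1, ]   # duplicated gene
  m[5, ] <- 2        # degenerate gene
  dec <- decompose_matrix(m, d, intensity = c(5, 4, 3, 2, 1))
  expect_equal(unlist(dec[3, 2:5]), unlist(dec[1, 2:5]))
  expect_true(dec$degenerate[5])
  expect_false(any(dec$degenerate[1:4]))
  fr1 <- nested_r2(m[2, ], d)
  expect_equal(unname(unlist(dec[2, 2:5])), unname(fr1))
  # fractions sum to one exactly after renormalization
  expect_equal(rowSums(as.matrix(dec[1:4, 2:5])), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gaussian and count variants agree on high-count data with little sampling noise", {
  p <- sim_params(n_genes = 2000, seq_total_reads = 5e6,
                  seq_extra_sigma_unit = 0.15,
                  de_logfc = list(type = "normal", mean = 0, sd = 0.5),
                  baseline_log_abundance = list(mean = 6, sd = 1),
                  seed = 104)
  tr <- simulate_truth(p)
  cc <- simulate_counts(tr, p)
  d <- p$design
  dec_g <- decompose_matrix(normalize_matrix(cc), d,
                            intensity = cc$intensity)
  dec_c <- decompose_matrix(cc, d, variant = "count")
  ok <- !dec_g$degenerate & !dec_c$degenerate
  for (comp in c("fraction_condition", "fraction_biological",
                 "fraction_preparation", "fraction_residual"))
    expect_lt(abs(mean(dec_g[[comp]][ok]) - mean(dec_c[[comp]][ok])), 0.02)
})

test_that("intensity-flat noise yields flat smoothed decomposition tracks", {
  p <- flat_fraction_params(c(0.5, 0.1, 0.1, 0.3), n_genes = 3000,
                            seed = 105)
  tr <- simulate_truth(p)
  aa <- simulate_two_channel(tr, p)
  dec <- decompose_matrix(aa, p$design)
  ok <- !dec$degenerate
  for (comp in c("fraction_condition", "fraction_residual")) {
    trk <- smooth_over_intensity(dec[[comp]][ok],
                                 dec$intensity_quantile[ok])
    expect_lt(diff(range(trk$value)), 0.1)
  }
})

test_that("smoothing reproduces constants and linear trends, and bands behave", {
  set.seed(106)
  q <- runif(300)
  trk <- smooth_over_intensity(rep(0.4, 300), q)
  expect_lt(max(abs(trk$value - 0.4)), 1e-9)
  expect_true(all(trk$lower <= trk$value & trk$value <= trk$upper))
  # quadratic local fit reproduces the identity exactly
  trk2 <- smooth_over_intensity(q, q)
  inner <- trk2$quantile > 0.05 & trk2$quantile < 0.95
  expect_lt(max(abs(trk2$value - trk2$quantile)[inner]), 1e-6)
  expect_error(smooth_over_intensity(q, q, span = 1.5), "span")
  expect_error(smooth_over_intensity(rnorm(10), runif(10)), ">= 50")
})

test_that("bootstrap bands cover a noisy linear trend at most grid points", {
  set.seed(107)
  n <- 400
  q <- runif(n)
  y <- 0.2 + 0.5 * q + rnorm(n, 0, 0.1)
  trk <- smooth_over_intensity(y, q, ci = "bootstrap", B = 200, seed = 9)
  truth <- 0.2 + 0.5 * trk$quantile
  expect_gte(mean(trk$lower <= truth & truth <= trk$upper), 0.9)
})

test_that("binned platform tests detect constructed residual shifts and nothing else", {
  d <- canonical_design()
  p <- sim_params(n_genes = 1200, seed = 108)
  tr <- simulate_truth(p)
  aa <- simulate_two_channel(tr, p)
  dec <- decompose_matrix(aa, d)
  bt_same <- bin_platform_test(dec, dec, n_bins = 10)
  expect_true(all(bt_same$p[bt_same$tested] == 1))
  expect_true(all(bt_same$median_diff[bt_same$tested] == 0))
  # constant +0.2 shift in the residual fraction of platform A
  dec_shift <- dec
  dec_shift$fraction_residual <- pmin(dec$fraction_residual + 0.2, 1)
  bt <- bin_platform_test(dec_shift, dec, n_bins = 10)
  expect_true(all(bt$p[bt$tested] < 1e-6))
  expect_equal(bt$median_diff[bt$tested],
               rep(0.2, sum(bt$tested)), tolerance = 1e-6)
  # undersized bins are flagged, not tested
  small <- dec[1:25, ]
  bt_small <- bin_platform_test(small, small, n_bins = 10)
  expect_true(any(!bt_small$tested))
})
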
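test_that("min-quantile ranking follows average ranks, takes the lower platform, and is symmetric", {
  a <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  b <- setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  mq <- min_quantile(a, b)
  expect_equal(mq$min_quantile, c(0.25, 0.5, 0.5, 0.25))
  mq2 <- min_quantile(b, a)
  expect_equal(mq2$min_quantile, mq$min_quantile)
  # top-ranked in both -> min quantile 1
  both_top <- min_quantile(setNames(c(1, 2, 3, 9), paste0("g", 1:4)),
                           setNames(c(2, 1, 3, 8), paste0("g", 1:4)))
  expect_equal(mq_top <- both_top$min_quantile[4], 1)
  # ties share averaged ranks
  tied <- min_quantile(setNames(c(5, 5, 1, 9), paste0("g", 1:4)),
                       setNames(c(1, 2, 3, 4), paste0("g", 1:4)))
  expect_equal(tied$quantile_a[1], tied$quantile_a[2])
  expect_equal(tied$quantile_a[1], mean(c(2, 3)) / 4)
  expect_error(min_quantile(setNames(c(0, 1), c("a", "b")),
                            setNames(c(1, 1), c("a", "b"))), "positive")
})

test_that("rolling correlations match brute-force window recomputation and respect stride nesting", {
  set.seed(200)
  n <- 30
  g <- sprintf("g%02d", 1:n)
  x <- setNames(rnorm(n), g)
  y <- setNames(x + rnorm(n, 0, 0.5), g)
  ord <- min_quantile(setNames(runif(n, 1, 2), g),
                      setNames(runif(n, 1, 2), g))
  tr <- rolling_correlation(x, y, ord, window = 10, step = 1,
                            spearman_ci = "none")
  expect_equal(nrow(tr), n - 10 + 1)
  # brute force each window after the same ordering
  o <- order(ord$min_quantile, ord$gene)
  xs <- x[ord$gene][o]; ys <- y[ord$gene][o]
  for (s in c(1, 7, 21)) {
    i <- s:(s + 9)
    expect_equal(tr$pearson[s], cor(xs[i], ys[i]))
    expect_equal(tr$spearman[s], cor(xs[i], ys[i], method = "spearman"))
  }
  # step s results are a subsequence of step 1 results
  tr5 <- rolling_correlation(x, y, ord, window = 10, step = 5,
                             spearman_ci = "none")
  expect_equal(tr5$pearson, tr$pearson[seq(1, nrow(tr), 5)])
  # perfect and anti-perfect agreement
  tid <- rolling_correlation(x, x, ord, window = 10, spearman_ci = "none")
  expect_equal(tid$pearson, rep(1, nrow(tid)))
  expect_equal(tid$spearman, rep(1, nrow(tid)))
  tneg <- rolling_correlation(x, setNames(-x, g), ord, window = 10,
                              spearman_ci = "none")
  expect_equal(tneg$pearson, rep(-1, nrow(tneg)))
  expect_equal(tneg$spearman, rep(-1, nrow(tneg)))
  expect_error(rolling_correlation(x, y, ord, window = 40), "smaller window")
  expect_error(rolling_correlation(x, y, ord, window = 5), ">= 10")
  # confidence bands contain the point estimates
  trb <- rolling_correlation(x, y, ord, window = 10, step = 10, B = 50)
  expect_true(all(trb$pearson_lo <= trb$pearson &
                    trb$pearson <= trb$pearson_hi))
  expect_true(all(trb$spearman_lo <= trb$spearman &
                    trb$spearman <= trb$spearman_hi))
})

test_that("per-unit fold changes isolate unit noise and divergence tracks behave", {
  d <- canonical_design()
  p <- sim_params(n_genes = 600, array_sigma_unit = 0, sigma_ref = 0,
                  seed = 201)
  tr <- simulate_truth(p)
  aa <- simulate_two_channel(tr, p)
  fc <- unit_logfc(aa$values, d)
  # no unit noise: the two units give identical estimates, flat zero track
  expect_equal(fc[, 1], fc[, 2], tolerance = 1e-12)
  q <- tr$abundance_quantile
  rd <- replicate_divergence(fc[, 1], fc[, 2], q, window = 100, step = 50)
  expect_lt(max(abs(rd$track$value)), 1e-9)
  # noise with sd decreasing in quantile gives a decreasing track
  set.seed(202)
  fc2 <- fc[, 1] + rnorm(600, 0, 0.6 * (1.2 - q[names(fc[, 1])]))
  rd2 <- replicate_divergence(fc[, 1], fc2, q, window = 100, step = 50)
  expect_lt(cor(rd2$track$quantile, rd2$track$value, method = "spearman"),
            -0.9)
  expect_error(replicate_divergence(fc[, 1], fc[1:10, 2], q), "same genes")
})

test_that("low-intensity discordant-gene selection applies both the quantile and gap rules", {
  g <- sprintf("g%02d", 1:20)
  deA <- data.frame(gene = g, logfc = rep(0, 20))
  deB <- data.frame(gene = g, logfc = rep(0, 20))
  ranks <- data.frame(gene = g,
                      quantile_a = seq(0.05, 1, 0.05),
                      quantile_b = seq(0.05, 1, 0.05),
                      min_quantile = seq(0.05, 1, 0.05))
  expect_equal(nrow(select_discordant_low(deA, deB, ranks)), 0)
  # one gene at quantile 0.1 with gap 1.5, one high-intensity with gap 2
  deA$logfc[2] <- 1.5
  deA$logfc[19] <- 2
  sel <- select_discordant_low(deA, deB, ranks)
  expect_equal(sel$gene, "g02")
  expect_equal(sel$gap, 1.5)
  # a sub-threshold gap stays out
  deA$logfc[1] <- 0.9
  expect_equal(nrow(select_discordant_low(deA, deB, ranks)), 1)
})

test_that("qPCR fold changes match hand arithmetic on a two-gene table", {
  ct <- data.frame(
    gene = rep(c("gA", "gB"), each = 4),
    biological = rep(c("G1", "G2", "E1", "E2"), 2),
    condition = rep(c("G", "G", "E", "E"), 2),
    ct = c(20, 21, 23, 24,    # gA: 3 cycles lower in G -> log2(G/E) = +3
           30, 29, 27, 26))   # gB: 3 cycles higher in G -> -3
  fc <- qpcr_logfc(ct, numerator = "G")
  # centring by the per-replicate all-gene mean: gA deviations (-5,-4,-2,-1),
  # gB (+5,+4,+2,+1); fc = mean(E) - mean(G) of centred Ct
  expect_equal(unname(fc["gA"]), mean(c(-2, -1)) - mean(c(-5, -4)))
  expect_equal(unname(fc["gB"]), -3)
  bad <- ct[ct$condition == "G" | ct$gene == "gB", ]
  expect_error(qpcr_logfc(bad, numerator = "G"), "absent in one condition")
})

test_that("validation reports perfect and anti-perfect toys and platform bias contrasts", {
  g <- paste0("g", 1:5)
  fc <- setNames(c(-2, -1, 0, 1, 2), g)
  vr <- validation_report(fc, fc, setNames(-fc, g))
  expect_equal(vr$cor_a, 1)
  expect_equal(vr$cor_b, -1)
  expect_error(validation_report(fc[1:2], fc[1:2], fc[1:2]), ">= 3")
})
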
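test_that("pooling sums counts to one library per biological replicate and conserves reads", {
  d <- canonical_design()
  ones <- matrix(1L, 3, 16, dimnames = list(paste0("g", 1:3), d$sample))
  pooled <- pool_counts(expression_matrix(ones, "counts"), d)
  expect_equal(ncol(pooled$values), 4)
  expect_true(all(pooled$values == 4))
  cdes <- attr(pooled, "design")
  expect_equal(as.integer(table(cdes$condition)), c(2L, 2L))
  set.seed(1)
  cm <- matrix(rpois(16 * 20, 30), 20, 16,
               dimnames = list(paste0("g", 1:20), d$sample))
  pooled2 <- pool_counts(expression_matrix(cm, "counts"), d)
  expect_equal(rowSums(pooled2$values), rowSums(cm))   # conservation
  expect_error(pool_counts(expression_matrix(cm + 0.5, "logintensity",
                                             intensity = rowSums(cm)), d),
               "counts")
})

test_that("array averaging is the arithmetic mean within biological replicates", {
  d <- canonical_design()
  m <- matrix(0, 2, 16, dimnames = list(c("g1", "g2"), d$sample))
  # one biological replicate with columns 0,2,4,6 -> mean 3
  m[1, d$biological == "G1"] <- c(0, 2, 4, 6)
  avg <- average_array(expression_matrix(m, "logratio",
                                         intensity = c(1, 1)), d)
  expect_equal(ncol(avg$values), 4)
  expect_equal(unname(avg$values[1, "G1"]), 3)
  # identical replicate columns: averaging is the identity
  m2 <- matrix(rnorm(16 * 5), 5, 16, dimnames = list(paste0("g", 1:5),
                                                     d$sample))
  for (b in unique(d$biological))
    m2[, d$biological == b] <- m2[, which(d$biological == b)[1]]
  avg2 <- average_array(expression_matrix(m2, "logratio",
                                          intensity = rep(1, 5)), d)
  expect_equal(unname(avg2$values),
               unname(m2[, !duplicated(d$biological)]))
})

test_that("log-CPM matches its closed form, is monotone, and stabilizes under scaling", {
  expect_equal(log_cpm(matrix(0), lib_sizes = 1e6 - 1, prior = 0.5)[1, 1], -1)
  counts <- matrix(c(0, 5, 100, 2000, 10000), 5, 1,
                   dimnames = list(paste0("g", 1:5), "s"))
  lc <- log_cpm(counts, lib_sizes = 1e5)
  expect_true(all(diff(lc[, 1]) > 0))
  # the prior's influence vanishes as counts grow: rescaling counts and
  # library sizes by 10 moves high-count values by less than 1e-3
  big <- counts >= 1000
  lc10 <- log_cpm(counts * 10, lib_sizes = 1e6)
  expect_lt(max(abs(lc10[big] - lc[big])), 1e-3)
})

test_that("voom weights are flat for homoskedastic log-data and depth-increasing for Poisson counts", {
  set.seed(31)
  n <- 2000
  d <- canonical_design()
  mm <- model.matrix(~ factor(d$condition))
  # log-normal data with constant log-scale sd: no mean-variance trend
  a <- runif(n, 8, 14)
  hom <- round(2^(a + matrix(rnorm(n * 16, 0, 0.3), n, 16)))
  dimnames(hom) <- list(paste0("g", 1:n), d$sample)
  w_hom <- voom_weights(hom, mm)
  gene_w <- rowMeans(w_hom$weights)
  expect_lt(max(gene_w) / min(gene_w), 1.5)
  expect_true(all(w_hom$weights > 0))
  # Poisson counts: weight increases with depth
  mu <- 2^runif(n, 1, 9)
  pois <- matrix(rpois(n * 16, rep(mu, 16)), n, 16,
                 dimnames = dimnames(hom))
  keep <- rowSums(pois) > 0
  w_p <- voom_weights(pois[keep, ], mm)
  expect_gt(cor(rowMeans(log2(pois[keep, ] + 0.5)), rowMeans(w_p$weights),
                method = "spearman"), 0.9)
  expect_error(voom_weights(pois[1:50, 1:2], model.matrix(~ c(0, 1))),
               "residual degrees")
})

test_that("TMM factors match a brute-force doubly-trimmed weighted mean and absorb pure scaling", {
  base <- c(100, 150, 200, 250, 300, 400, 500, 600, 700, 800)
  y2 <- base; y2[c(3, 7)] <- base[c(3, 7)] * 8   # 20% of genes 8-fold up
  m <- cbind(s1 = base, s2 = y2)
  rownames(m) <- paste0("g", 1:10)
  f <- tmm_factors(m, ref_column = 1)
  n1 <- sum(base); n2 <- sum(y2)
  M <- log2((y2 / n2) / (base / n1))
  A <- (log2(y2 / n2) + log2(base / n1)) / 2
  w <- 1 / ((n2 - y2) / (n2 * y2) + (n1 - base) / (n1 * base))
  loM <- floor(10 * 0.3) + 1; hiM <- 10 + 1 - loM
  loA <- floor(10 * 0.05) + 1; hiA <- 10 + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  raw <- 2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  oracle <- c(1, raw) / exp(mean(log(c(1, raw))))
  expect_lt(max(abs(f - oracle)), 1e-10)
  expect_equal(unname(tmm_factors(cbind(a = base, b = base))), c(1, 1))
  expect_equal(unname(tmm_factors(cbind(a = base, b = 2 * base))), c(1, 1))
  expect_error(tmm_factors(cbind(a = base, b = 0 * base)), "no counts")
})

test_that("RLE factors are median count-to-geometric-mean ratios rescaled to geometric mean one", {
  m5 <- matrix(c(12, 20, 33, 47, 50, 24, 40, 66, 94, 100), 5, 2,
               dimnames = list(paste0("g", 1:5), c("a", "b")))
  # column b is 2x column a: ratio of factors is 2, geometric mean 1
  f <- rle_factors(m5)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  # brute-force hand computation on an asymmetric toy
  m <- matrix(c(10, 100, 40, 7, 90, 30, 80, 130, 21, 55, 11, 70), 4, 3,
              dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  geo <- exp(rowMeans(log(m)))
  raw <- apply(m, 2, function(col) median(col / geo))
  expect_equal(unname(rle_factors(m)), unname(raw / exp(mean(log(raw)))))
  expect_equal(unname(rle_factors(cbind(a = m[, 1], b = m[, 1]))), c(1, 1))
  expect_error(rle_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                  dimnames = list(c("g1", "g2"),
                                                  c("a", "b")))),
               "all-positive")
})

test_that("all scaling-factor sets have geometric mean one", {
  set.seed(77)
  m <- matrix(rpois(6 * 300, 2^runif(300, 2, 10)), 300, 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  expect_equal(exp(mean(log(tmm_factors(m)))), 1, tolerance = 1e-12)
  expect_equal(exp(mean(log(rle_factors(m)))), 1, tolerance = 1e-12)
})

test_that("quantile normalization equalizes column distributions with mean order statistics", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  set.seed(4)
  y <- matrix(rnorm(500), 100, 5)
  qn2 <- quantile_normalize(y)
  expect_lt(diff(range(colMeans(qn2))), 1e-12)
  same <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)
})
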
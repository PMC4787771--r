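#' Simulation parameters for a paired-platform nested experiment
#'
#' Defines the ground-truth generative model shared by the two simulated
#' platforms.  Per-gene log2 abundance is Gaussian; a fraction of genes
#' carry a condition log2 fold change (log2(G/E)); biological-replicate
#' and preparation random effects are Gaussian on the log2 scale and are
#' shared between platforms (the same RNA feeds both); chip/lane noise is
#' platform-specific.  RNA-seq counts are Poisson samples at a fixed lane
#' read total after a lognormal per-gene-per-lane overdispersion factor;
#' array log-ratios get additive Gaussian chip noise whose sd interpolates
#' log-linearly between a low- and a high-abundance value (a scalar gives
#' intensity-flat noise).
#'
#' Defaults emulate the canonical 16-sample design at desk scale: 5000
#' genes, 200k reads per lane-sample, log2 abundance spread sd 2,
#' biological and preparation sds 0.1, lane overdispersion sd 0.05, and
#' chip noise falling from 0.22 to 0.12 across the abundance range so that
#' the two platforms' unit-level noise converges near the top intensity
#' decile.
#'
#' @param n_genes number of genes.
#' @param design a [nested_design]; default [canonical_design()].
#' @param baseline_log_abundance list(mean, sd) of per-gene log2 abundance.
#' @param prop_de fraction of genes with a nonzero condition effect.
#' @param de_logfc condition effect distribution: list(type = "normal",
#'   mean, sd) or list(type = "fixed", magnitude) with random sign.
#' @param sigma_bio,sigma_prep biological / preparation random-effect sds
#'   (log2 scale).
#' @param array_sigma_unit chip-level log2 noise sd; scalar (flat) or
#'   length-2 c(lo, hi) interpolated log-linearly in abundance quantile.
#' @param sigma_ref sd of the per-gene array reference-channel noise.
#' @param seq_total_reads target reads per lane-sample.
#' @param seq_extra_sigma_unit lane-level overdispersion sd (log2 scale).
#' @param bias_spec optional [bias_spec()] describing systematic
#'   low-intensity biases, or NULL.
#' @param fluor_range fluorescence range that array intensities are
#'   rescaled into.
#' @param seed integer seed; every simulation routine derives its RNG
#'   state from it.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(n_genes = 5000,
                       design = canonical_design(),
                       baseline_log_abundance = list(mean = 4, sd = 2),
                       prop_de = 0.2,
                       de_logfc = list(type = "normal", mean = 0, sd = 1),
                       sigma_bio = 0.1,
                       sigma_prep = 0.1,
                       array_sigma_unit = c(0.22, 0.12),
                       sigma_ref = 0.05,
                       seq_total_reads = 2e5,
                       seq_extra_sigma_unit = 0.05,
                       bias_spec = NULL,
                       fluor_range = c(100, 60000),
                       seed = 1L) {
  stopifnot(n_genes >= 1, inherits(design, "nested_design"),
            prop_de >= 0, prop_de <= 1,
            sigma_bio >= 0, sigma_prep >= 0, all(array_sigma_unit >= 0),
            sigma_ref >= 0, seq_total_reads > 0, seq_extra_sigma_unit >= 0,
            baseline_log_abundance$sd >= 0)
  if (length(array_sigma_unit) == 1)
    array_sigma_unit <- rep(array_sigma_unit, 2)
  structure(list(n_genes = as.integer(n_genes), design = design,
                 baseline_log_abundance = baseline_log_abundance,
                 prop_de = prop_de, de_logfc = de_logfc,
                 sigma_bio = sigma_bio, sigma_prep = sigma_prep,
                 array_sigma_unit = array_sigma_unit, sigma_ref = sigma_ref,
                 seq_total_reads = seq_total_reads,
                 seq_extra_sigma_unit = seq_extra_sigma_unit,
                 bias_spec = bias_spec, fluor_range = fluor_range,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Systematic low-intensity bias specification
#'
#' Assigns a platform-specific additive log2 fold-change offset to a set
#' of low-abundance genes, emulating e.g. cross-hybridization artifacts
#' that corrupt one platform's fold-change estimates.
#'
#' @param n_genes number of genes to bias.
#' @param max_quantile genes are drawn from abundance quantiles at or
#'   below this value.
#' @param magnitude absolute offset added to the affected genes' log2
#'   fold change on the chosen platform.
#' @param sign "random" (each gene +/- with equal probability),
#'   "positive" or "negative".
#' @param platform which platform is biased ("logratio" or "counts").
#' @export
bias_spec <- function(n_genes = 13, max_quantile = 0.2, magnitude = 1.5,
                      sign = c("random", "positive", "negative"),
                      platform = c("logratio", "counts")) {
  list(n_genes = as.integer(n_genes), max_quantile = max_quantile,
       magnitude = magnitude, sign = match.arg(sign),
       platform = match.arg(platform))
}

# chip noise sd per gene from its abundance quantile (log-linear in q)
.array_sigma <- function(params, q) {
  lo <- params$array_sigma_unit[1]; hi <- params$array_sigma_unit[2]
  if (lo == 0 || hi == 0) return(rep(0, length(q)))
  lo * (hi / lo)^q
}

# (log2 e)^2: variance on the log2 scale of a unit-variance relative error
.LOG2E2 <- 1 / log(2)^2

#' Draw the ground truth of a simulated experiment
#'
#' Deterministic given \code{params$seed}.  Exactly
#' \code{round(prop_de * n_genes)} genes receive a nonzero condition
#' effect.  Realized biological and preparation random effects are drawn
#' here once and shared by both platforms; per-gene implied true variance
#' fractions are recorded for each platform (for counts the Poisson
#' sampling contribution is approximated from the expected mean count).
#'
#' @param params a [sim_params()].
#' @return A list of class \code{sim_truth}.
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  design <- params$design
  genes <- sprintf("g%04d", seq_len(n))
  a <- stats::rnorm(n, params$baseline_log_abundance$mean,
                    params$baseline_log_abundance$sd)
  n_de <- round(params$prop_de * n)
  de <- rep(FALSE, n)
  de[sample.int(n, n_de)] <- TRUE
  beta <- numeric(n)
  if (n_de > 0) {
    spec <- params$de_logfc
    beta[de] <- switch(spec$type,
      normal = stats::rnorm(n_de, spec$mean, spec$sd),
      fixed  = spec$magnitude * sample(c(-1, 1), n_de, replace = TRUE),
      stop("unknown de_logfc type '", spec$type, "'"))
  }
  bios  <- unique(design$biological)
  preps <- unique(design$preparation)
  bio_eff <- matrix(stats::rnorm(n * length(bios), 0, params$sigma_bio),
                    n, length(bios), dimnames = list(genes, bios))
  prep_eff <- matrix(stats::rnorm(n * length(preps), 0, params$sigma_prep),
                     n, length(preps), dimnames = list(genes, preps))
  ref_noise <- stats::rnorm(n, 0, params$sigma_ref)
  q <- rank(a, ties.method = "average") / n

  bias <- numeric(n)
  if (!is.null(params$bias_spec)) {
    bs <- params$bias_spec
    pool <- which(q <= bs$max_quantile)
    if (length(pool) < bs$n_genes)
      stop("not enough low-abundance genes to bias")
    pick <- sample(pool, bs$n_genes)
    sgn <- switch(bs$sign,
                  random = sample(c(-1, 1), bs$n_genes, replace = TRUE),
                  positive = 1, negative = -1)
    bias[pick] <- sgn * bs$magnitude
  }

  # implied per-gene true variance fractions, per platform
  v_cond <- beta^2 / 4
  v_bio  <- rep(params$sigma_bio^2, n)
  v_prep <- rep(params$sigma_prep^2, n)
  v_arr  <- .array_sigma(params, q)^2
  mu_bar <- .expected_counts(a, beta, design, params$seq_total_reads)
  v_seq  <- params$seq_extra_sigma_unit^2 + .LOG2E2 / pmax(mu_bar, 1e-8)
  frac <- list(
    logratio = .fractions(v_cond, v_bio, v_prep, v_arr),
    counts   = .fractions(v_cond, v_bio, v_prep, v_seq)
  )
  structure(list(genes = genes, a = setNames(a, genes),
                 beta = setNames(beta, genes), de = setNames(de, genes),
                 bio_eff = bio_eff, prep_eff = prep_eff,
                 ref_noise = setNames(ref_noise, genes),
                 abundance_quantile = setNames(q, genes),
                 bias = setNames(bias, genes),
                 bias_platform = if (is.null(params$bias_spec)) NA_character_
                                 else params$bias_spec$platform,
                 expected_mean_count = setNames(mu_bar, genes),
                 frac = frac, params = params),
            class = "sim_truth")
}

.fractions <- function(...) {
  m <- cbind(...)
  colnames(m) <- c("condition", "biological", "preparation", "residual")
  m / rowSums(m)
}

# expected count per gene averaged over samples, from the noise-free signal
.expected_counts <- function(a, beta, design, reads) {
  ind <- .condition_indicator(design)
  s <- outer(a, rep(1, nrow(design))) + outer(beta, ind)
  p <- 2^s
  p <- sweep(p, 2, colSums(p), "/")
  rowMeans(p) * reads
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$genes), "genes,", sum(x$de),
      "differentially expressed,", sum(x$bias != 0), "biased\n")
  invisible(x)
}

# noise-free log2 signal matrix (gene x sample): baseline + condition +
# biological + preparation effects
.signal_matrix <- function(truth, design) {
  ind <- .condition_indicator(design)
  s <- outer(truth$a, rep(1, nrow(design))) + outer(truth$beta, ind) +
    truth$bio_eff[, design$biological, drop = FALSE] +
    truth$prep_eff[, design$preparation, drop = FALSE]
  dimnames(s) <- list(truth$genes, design$sample)
  s
}

#' Simulate RNA-seq counts for the nested design
#'
#' Per sample, expected gene proportions are proportional to
#' \code{2^(signal + lane overdispersion draw)}; counts are independent
#' Poisson draws at the lane read total (default) or a single multinomial
#' draw per sample.
#'
#' @param truth a [simulate_truth()] result.
#' @param params the same [sim_params()].
#' @param scheme "poisson" (default) or "multinomial".
#' @return An [expression_matrix()] with platform "counts"; intensity is
#'   the per-gene total read count.
#' @export
simulate_counts <- function(truth, params, scheme = c("poisson",
                                                      "multinomial")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(params$seed + 1L)
  design <- params$design
  s <- .signal_matrix(truth, design)
  if (identical(truth$bias_platform, "counts")) {
    ind <- .condition_indicator(design)
    s <- s + outer(truth$bias, ind)
  }
  n <- nrow(s); m <- ncol(s)
  if (params$seq_extra_sigma_unit > 0)
    s <- s + matrix(stats::rnorm(n * m, 0, params$seq_extra_sigma_unit), n, m)
  p <- 2^s
  p <- sweep(p, 2, colSums(p), "/")
  mu <- p * params$seq_total_reads
  counts <- if (scheme == "poisson") {
    matrix(stats::rpois(n * m, mu), n, m, dimnames = dimnames(s))
  } else {
    cm <- vapply(seq_len(m), function(j)
      stats::rmultinom(1, params$seq_total_reads, p[, j])[, 1],
      numeric(n))
    dimnames(cm) <- dimnames(s)
    cm
  }
  expression_matrix(counts, platform = "counts")
}

#' Simulate two-channel microarray log-ratios for the nested design
#'
#' The sample (cy5) channel carries the noise-free signal plus chip noise;
#' the reference channel is modelled as the mean of the two condition
#' means plus a small per-gene noise, so log-ratios are centred around
#' +/- half the condition effect.  Fluorescence intensity is the per-gene
#' baseline abundance rescaled monotonically into \code{fluor_range}.
#'
#' @inheritParams simulate_counts
#' @return An [expression_matrix()] with platform "logratio".
#' @export
simulate_two_channel <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(params$seed + 2L)
  design <- params$design
  s <- .signal_matrix(truth, design)
  ref <- truth$a + truth$beta / 2 + truth$ref_noise
  ratio <- s - ref
  sd_g <- .array_sigma(params, truth$abundance_quantile)
  n <- nrow(s); m <- ncol(s)
  ratio <- ratio + matrix(stats::rnorm(n * m, 0, sd_g), n, m)
  if (identical(truth$bias_platform, "logratio")) {
    ind <- .condition_indicator(design)
    ratio <- ratio + outer(truth$bias, ind)
  }
  ab <- 2^truth$a
  lo <- params$fluor_range[1]; hi <- params$fluor_range[2]
  intensity <- lo + (hi - lo) * (ab - min(ab)) / (max(ab) - min(ab))
  expression_matrix(ratio, platform = "logratio", intensity = intensity)
}

#' Simulate qPCR cycle-threshold replicates
#'
#' Ct values are inversely linear in log2 abundance (one PCR cycle = one
#' log2 unit; lower Ct = more abundant), with a per-biological-sample
#' plate offset and Gaussian replicate noise.  By default the biological
#' random effects are omitted so that with \code{sigma_ct = 0} the
#' condition delta-Ct recovers the true condition effect exactly.
#'
#' @param truth a [simulate_truth()] result.
#' @param genes gene ids to assay (must exist in the truth).
#' @param n_reps technical replicates per biological sample (default 3).
#' @param sigma_ct replicate noise sd in cycles.
#' @param seed integer seed.
#' @param include_bio include the realized biological random effects in
#'   the assayed abundance.
#' @return data.frame with columns gene, biological, condition,
#'   replicate, ct.
#' @export
simulate_qpcr <- function(truth, genes, n_reps = 3, sigma_ct = 0.15,
                          seed = truth$params$seed + 3L,
                          include_bio = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  unknown <- setdiff(genes, truth$genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  design <- truth$params$design
  bio_tab <- unique(design[, c("biological", "condition")])
  offsets <- stats::rnorm(nrow(bio_tab), 30, 2)
  rows <- expand.grid(gene = genes, b = seq_len(nrow(bio_tab)),
                      replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ind <- as.numeric(bio_tab$condition[rows$b] ==
                    unique(design$condition)[1])
  abund <- truth$a[rows$gene] + truth$beta[rows$gene] * ind
  if (include_bio)
    abund <- abund + truth$bio_eff[cbind(rows$gene,
                                         bio_tab$biological[rows$b])]
  ct <- offsets[rows$b] - abund + stats::rnorm(nrow(rows), 0, sigma_ct)
  data.frame(gene = rows$gene,
             biological = bio_tab$biological[rows$b],
             condition = bio_tab$condition[rows$b],
             replicate = rows$replicate,
             ct = as.numeric(ct),
             stringsAsFactors = FALSE)
}

#' Simulate intensity-coherent gene sets
#'
#' Real gene sets tend to be expression-coherent (e.g. ribosomal sets are
#' uniformly highly expressed), which is what makes intensity a confounder
#' for rank-based enrichment.  Each simulated set draws its members from a
#' window of the abundance-quantile scale around a random centre.
#'
#' @param truth a [simulate_truth()] result.
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @param bandwidth half-width of the quantile window members are drawn
#'   from.
#' @param seed integer seed.
#' @return A \code{gene_set_collection} (named list of gene id vectors).
#' @export
simulate_gene_sets <- function(truth, n_sets = 200, set_size = 30,
                               bandwidth = 0.1,
                               seed = truth$params$seed + 4L) {
  set.seed(seed)
  q <- truth$abundance_quantile
  sets <- vector("list", n_sets)
  centers <- stats::runif(n_sets)
  for (i in seq_len(n_sets)) {
    ctr <- min(max(centers[i], bandwidth), 1 - bandwidth)
    pool <- names(q)[abs(q - ctr) <= bandwidth]
    sets[[i]] <- sample(pool, min(set_size, length(pool)))
  }
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  structure(sets,
            description = setNames(sprintf("centre %.2f", centers),
                                   names(sets)),
            class = "gene_set_collection")
}

#' Simulate a complete paired-platform experiment
#'
#' @param params a [sim_params()].
#' @return list with elements \code{truth}, \code{counts}, \code{arrays},
#'   \code{design}.
#' @export
simulate_experiment <- function(params = sim_params()) {
  truth <- simulate_truth(params)
  list(truth = truth,
       counts = simulate_counts(truth, params),
       arrays = simulate_two_channel(truth, params),
       design = params$design)
}

#' Parameters realizing intensity-flat target variance fractions
#'
#' Builds a [sim_params()] whose implied per-gene variance fractions equal
#' the given targets uniformly across intensity on both platforms: every
#' gene is differentially expressed with a fixed-magnitude random-sign
#' condition effect, chip noise is flat, and sequencing depth is high
#' enough that Poisson sampling noise is negligible next to the lane
#' overdispersion.  Used for parameter-recovery calibration.
#'
#' @param fractions length-4 numeric (condition, biological, preparation,
#'   unit) summing to 1.
#' @param n_genes number of genes.
#' @param total_sd total per-gene log2 sd realizing the fractions.
#' @param seed integer seed.
#' @export
flat_fraction_params <- function(fractions = c(0.5, 0.1, 0.1, 0.3),
                                 n_genes = 5000, total_sd = 0.6,
                                 seed = 1L) {
  stopifnot(length(fractions) == 4, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  v <- fractions * total_sd^2
  sim_params(
    n_genes = n_genes,
    baseline_log_abundance = list(mean = 4, sd = 1),
    prop_de = 1,
    de_logfc = list(type = "fixed", magnitude = 2 * sqrt(v[1])),
    sigma_bio = sqrt(v[2]),
    sigma_prep = sqrt(v[3]),
    array_sigma_unit = sqrt(v[4]),
    sigma_ref = 0.05,
    seq_total_reads = 1e7,
    seq_extra_sigma_unit = sqrt(v[4]),
    seed = seed
  )
}
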
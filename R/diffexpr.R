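#' Gene-wise weighted two-group linear models
#'
#' Weighted least squares of each gene's (pooled or averaged) values on
#' the condition contrast.  The coefficient is the fitted log2(G/E)
#' difference (numerator condition minus the other).
#'
#' @param x a \code{weighted_log_matrix} (from [normalize_matrix()] /
#'   [voom_weights()]) or a numeric matrix (unit weights).
#' @param condition per-sample condition labels (2 levels); the first
#'   unique label (or \code{numerator}) is the numerator of the contrast.
#' @param numerator optional condition label to use as numerator.
#' @return list of class \code{gene_fits}: per-gene \code{coef},
#'   \code{s2} (residual variance), \code{df}, \code{stdev_unscaled},
#'   \code{amean} (mean log2 value).
#' @export
fit_gene_models <- function(x, condition, numerator = NULL) {
  if (inherits(x, "weighted_log_matrix")) {
    Y <- x$log2; W <- x$weights
  } else {
    Y <- as.matrix(x); W <- array(1, dim(Y), dimnames(Y))
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(Y))
    stop("condition labels must match the matrix columns")
  lev <- unique(condition)
  if (length(lev) != 2) stop("exactly 2 condition levels required (singular design otherwise)")
  if (is.null(numerator)) numerator <- lev[1]
  if (min(table(condition)) < 2)
    stop(">= 2 samples per condition required")
  g1 <- condition == numerator
  sw1 <- rowSums(W[, g1, drop = FALSE]); sw2 <- rowSums(W[, !g1, drop = FALSE])
  m1 <- rowSums((W * Y)[, g1, drop = FALSE]) / sw1
  m2 <- rowSums((W * Y)[, !g1, drop = FALSE]) / sw2
  fitted <- outer(m1, as.numeric(g1)) + outer(m2, as.numeric(!g1))
  rss <- rowSums(W * (Y - fitted)^2)
  df <- ncol(Y) - 2
  s2 <- rss / df
  structure(list(coef = m1 - m2, s2 = s2, df = rep(df, nrow(Y)),
                 stdev_unscaled = sqrt(1 / sw1 + 1 / sw2),
                 amean = rowMeans(Y), genes = rownames(Y)),
            class = "gene_fits")
}

#' Empirical-Bayes variance moderation
#'
#' Estimates a prior df \code{d0} and prior variance \code{s0^2} by
#' fitting a scaled F-distribution to the gene-wise residual variances
#' (the moments-on-log-s2 procedure of the moderated-t method), forms
#' posterior variances \code{(d0 s0^2 + df s^2) / (d0 + df)}, and returns
#' moderated t-statistics on \code{df + d0} degrees of freedom.
#'
#' @param fits a \code{gene_fits} object (or a list with coef, s2, df,
#'   stdev_unscaled).
#' @param force_d0 optional override of the prior df: 0 recovers the
#'   ordinary t-test, \code{Inf} fully shrinks every variance to
#'   \code{s0^2}.
#' @return list of class \code{eb_fit}: d0, s0_2, var_post, t, p (two
#'   sided), df_total.
#' @export
eb_moderate <- function(fits, force_d0 = NULL) {
  s2 <- fits$s2; df <- fits$df
  if (sum(df > 0) < 10) stop("need >= 10 genes with positive residual df")
  if (all(s2 == 0)) stop("all residual variances are zero: no variance information")
  fd <- limma::fitFDist(s2, df1 = df)
  d0 <- fd$df2; s0_2 <- fd$scale
  if (!is.null(force_d0)) d0 <- force_d0
  var_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  t <- fits$coef / (fits$stdev_unscaled * sqrt(var_post))
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  structure(list(d0 = d0, s0_2 = s0_2, var_post = var_post,
                 t = t, p = p, df_total = df_total, coef = fits$coef,
                 genes = fits$genes, amean = fits$amean),
            class = "eb_fit")
}

#' False discovery rate estimation
#'
#' Storey q-values with the smoother estimate of pi0 (the proportion of
#' null genes; natural cubic smoothing spline of pi0(lambda) over lambda
#' = 0.05, ..., 0.95 evaluated at 0.95), or Benjamini-Hochberg step-up
#' adjusted p-values.  Forcing pi0 = 1 makes the q-values equal BH.
#'
#' @param p p-values in [0, 1].
#' @param method "storey" (default) or "bh".
#' @param pi0 optional fixed pi0 overriding the smoother estimate.
#' @return adjusted values, same length and order as \code{p}.
#' @export
fdr <- function(p, method = c("storey", "bh"), pi0 = NULL) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1] with no NAs")
  if (method == "bh") return(stats::p.adjust(p, "BH"))
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[order(o)]
}

#' @describeIn fdr smoother estimate of the null proportion pi0.
#' @param lambda grid of tuning values.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Differential expression table for one platform
#'
#' Runs the platform's replicate-reduction, normalization, gene-wise
#' weighted linear model, empirical-Bayes moderation and FDR estimation,
#' and returns the per-gene table used by every downstream comparison.
#' Counts are pooled to biological replicates, normalized ("tmm", "rle"
#' or "none") and voom-weighted; arrays are averaged to biological
#' replicates and optionally quantile-normalized.  Genes below
#' \code{min_count} total reads are dropped for counts.
#'
#' @param x an [expression_matrix()] (16 unpooled samples).
#' @param design the matching [nested_design].
#' @param norm normalization method passed to the platform path.
#' @param numerator condition treated as the fold-change numerator
#'   (default the design's first condition, conventionally "G").
#' @param min_count minimum total count for a gene to be tested (counts
#'   platform only).
#' @param fdr_method "storey" or "bh".
#' @return data.frame of class \code{de_table}: gene, logfc, t, p,
#'   q (Storey), p_bh, mean_intensity, df, plus attributes \code{d0},
#'   \code{s0_2}, \code{platform}.
#' @export
de_table <- function(x, design, norm = NULL, numerator = NULL,
                     min_count = 16, fdr_method = "storey") {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$platform == "counts") {
    if (is.null(norm)) norm <- "tmm"
    pooled <- pool_counts(x, design)
    keep <- rowSums(pooled$values) >= min_count
    pooled <- expression_matrix(pooled$values[keep, , drop = FALSE],
                                platform = "counts",
                                intensity = pooled$intensity[keep])
    cdes <- .collapse_design(design)
    mm <- stats::model.matrix(~ factor(cdes$condition,
                                       levels = unique(cdes$condition)))
    norm_method <- if (norm %in% c("tmm", "rle", "none")) norm else "none"
    lib <- colSums(pooled$values)
    eff <- switch(norm_method,
                  tmm = lib * tmm_factors(pooled),
                  rle = rle_factors(pooled) * exp(mean(log(lib))),
                  none = lib)
    wlm <- voom_weights(pooled, mm, lib_sizes = eff)
    fits <- fit_gene_models(wlm, cdes$condition, numerator = numerator)
    intensity <- pooled$intensity
  } else {
    if (is.null(norm)) norm <- "quantile"
    avg <- average_array(x, design)
    v <- if (norm == "quantile") quantile_normalize(avg$values) else
      avg$values
    cdes <- .collapse_design(design)
    fits <- fit_gene_models(v, cdes$condition, numerator = numerator)
    intensity <- avg$intensity
  }
  if (fits$df[1] < 3)
    warning("residual df < 3: empirical-Bayes moderation dominates the ",
            "per-gene variances")
  eb <- eb_moderate(fits)
  q <- fdr(eb$p, method = fdr_method)
  out <- data.frame(gene = fits$genes, logfc = eb$coef, t = eb$t, p = eb$p,
                    q = q, p_bh = stats::p.adjust(eb$p, "BH"),
                    mean_intensity = as.numeric(intensity),
                    df = fits$df, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"),
            d0 = eb$d0, s0_2 = eb$s0_2, platform = x$platform)
}

#' @export
print.de_table <- function(x, ...) {
  cat("Differential expression (", attr(x, "platform"), "): ", nrow(x),
      " genes tested, ", sum(x$q <= 0.05), " at q <= 0.05; prior df = ",
      format(attr(x, "d0"), digits = 4), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  invisible(x)
}
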
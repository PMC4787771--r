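#' Shared intensity ranking across platforms
#'
#' Each gene's intensity quantile is computed within each platform via
#' average ranks scaled to (0, 1], and the per-gene minimum of the two
#' ("the quantile of the intensity in microarray or RNA-seq, whichever is
#' lower") is the shared ranking used for cross-platform comparisons.
#'
#' @param intensA,intensB named per-gene positive intensities from the
#'   two platforms (matched on names if present; otherwise positional).
#' @return data.frame of class \code{intensity_rank}: gene, quantile_a,
#'   quantile_b, min_quantile.
#' @export
min_quantile <- function(intensA, intensB) {
  if (!is.null(names(intensA)) && !is.null(names(intensB))) {
    shared <- intersect(names(intensA), names(intensB))
    dropped <- length(intensA) - length(shared)
    if (dropped > 0 || length(intensB) > length(shared))
      message("min_quantile: ",
              (length(intensA) - length(shared)) +
                (length(intensB) - length(shared)),
              " gene(s) absent from one platform discarded")
    intensA <- intensA[shared]; intensB <- intensB[shared]
    genes <- shared
  } else {
    if (length(intensA) != length(intensB))
      stop("unnamed intensity vectors must have equal length")
    genes <- paste0("g", seq_along(intensA))
  }
  if (any(intensA <= 0) || any(intensB <= 0))
    stop("intensities must be positive")
  qa <- rank(intensA, ties.method = "average") / length(intensA)
  qb <- rank(intensB, ties.method = "average") / length(intensB)
  structure(data.frame(gene = genes, quantile_a = qa, quantile_b = qb,
                       min_quantile = pmin(qa, qb),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("intensity_rank", "data.frame"))
}

#' Rolling-window correlation along an intensity ranking
#'
#' Genes are sorted by the shared min-quantile; within each full window
#' of \code{window} genes (advancing by \code{step}; partial edge windows
#' are dropped) the Pearson and Spearman correlations of the two per-gene
#' value vectors are computed with 95% confidence bands (Fisher z for
#' Pearson; a seeded gene-resampling bootstrap for Spearman).
#'
#' @param x,y named per-gene values (e.g. log2 fold changes from the two
#'   platforms).
#' @param order an \code{intensity_rank} from [min_quantile()] (or any
#'   data.frame with gene and min_quantile columns).
#' @param window window size in genes (>= 10), default 500.
#' @param step stride between window starts, default 1.
#' @param spearman_ci "bootstrap" or "none".
#' @param B bootstrap replicates for the Spearman band.
#' @param seed bootstrap seed.
#' @return data.frame of class \code{correlation_track}: center_rank,
#'   center_quantile, n, pearson, pearson_lo, pearson_hi, spearman,
#'   spearman_lo, spearman_hi.
#' @export
rolling_correlation <- function(x, y, order, window = 500, step = 1,
                                spearman_ci = c("bootstrap", "none"),
                                B = 200, seed = 1L) {
  spearman_ci <- match.arg(spearman_ci)
  if (window < 10) stop("window must be >= 10")
  genes <- order$gene
  if (!all(genes %in% names(x)) || !all(genes %in% names(y)))
    stop("x and y must be named and cover the ranked genes")
  o <- base::order(order$min_quantile, genes)
  genes <- genes[o]
  qs <- order$min_quantile[o]
  xv <- as.numeric(x[genes]); yv <- as.numeric(y[genes])
  n <- length(genes)
  if (n < window)
    stop("fewer genes (", n, ") than the window (", window,
         "); use a smaller window")
  starts <- seq(1L, n - window + 1L, by = step)
  set.seed(seed)
  rows <- lapply(starts, function(s) {
    i <- s:(s + window - 1L)
    xi <- xv[i]; yi <- yv[i]
    r <- stats::cor(xi, yi)
    z <- atanh(r); hw <- 1.96 / sqrt(window - 3)
    rho <- stats::cor(xi, yi, method = "spearman")
    if (spearman_ci == "bootstrap") {
      bs <- vapply(seq_len(B), function(b) {
        idx <- sample.int(window, window, replace = TRUE)
        stats::cor(xi[idx], yi[idx], method = "spearman")
      }, numeric(1))
      slo <- min(stats::quantile(bs, 0.025, na.rm = TRUE), rho)
      shi <- max(stats::quantile(bs, 0.975, na.rm = TRUE), rho)
    } else {
      slo <- NA_real_; shi <- NA_real_
    }
    data.frame(center_rank = s + (window - 1) / 2,
               center_quantile = qs[s + (window - 1L) %/% 2L],
               n = window,
               pearson = r, pearson_lo = tanh(z - hw),
               pearson_hi = tanh(z + hw),
               spearman = rho, spearman_lo = slo, spearman_hi = shi)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("correlation_track", "data.frame"))
}

#' Per-unit log2 fold changes
#'
#' For each chip or lane (unit label), the condition log2(G/E) estimate
#' computed from only that unit's samples -- the same preparations run on
#' both units, so differencing the two units' estimates isolates the
#' chip/lane noise.  Estimates are simple mean differences of the
#' supplied normalized log-scale values (no moderation, which would share
#' information across units and blur the unit contrast).
#'
#' @param log_values gene x sample matrix of normalized log2-scale values
#'   (log-CPM for counts, log-ratios for arrays), unpooled.
#' @param design the matching [nested_design].
#' @param numerator condition label used as numerator.
#' @return gene x unit matrix of log2 fold changes.
#' @export
unit_logfc <- function(log_values, design, numerator = NULL) {
  if (inherits(log_values, "weighted_log_matrix"))
    log_values <- log_values$log2
  log_values <- as.matrix(log_values)
  .stopifnot_samples(log_values, design)
  lev <- unique(design$condition)
  if (is.null(numerator)) numerator <- lev[1]
  units <- unique(design$unit)
  fc <- vapply(units, function(u) {
    in_u <- design$unit == u
    g <- in_u & design$condition == numerator
    e <- in_u & design$condition != numerator
    rowMeans(log_values[, g, drop = FALSE]) -
      rowMeans(log_values[, e, drop = FALSE])
  }, numeric(nrow(log_values)))
  colnames(fc) <- units
  fc
}

.stopifnot_samples <- function(m, design) {
  if (ncol(m) != nrow(design) ||
      !identical(colnames(m), design$sample))
    stop("matrix samples do not match the design")
  invisible(TRUE)
}

#' Replicate fold-change divergence over intensity
#'
#' Smooths the absolute difference between the two units' fold-change
#' estimates (|fc1 - fc2|) over the intensity quantile with a confidence
#' band, and also returns the rolling correlation between the two units'
#' estimates.
#'
#' @param fc1,fc2 named per-gene log2 fold changes from the two chips or
#'   lanes (same gene set).
#' @param quantiles named per-gene intensity quantiles.
#' @param span LOESS span.
#' @param window,step rolling-correlation window and stride.
#' @param ... passed to [smooth_over_intensity()].
#' @return list with \code{track} (a \code{smoothed_track} of
#'   |fc1 - fc2|) and \code{correlation} (a \code{correlation_track}).
#' @export
replicate_divergence <- function(fc1, fc2, quantiles, span = 0.75,
                                 window = 500, step = 1, ...) {
  if (!identical(names(fc1), names(fc2)))
    stop("fc1 and fc2 must cover the same genes in the same order")
  if (is.null(names(fc1)) || !all(names(fc1) %in% names(quantiles)))
    stop("fold changes and quantiles must be named consistently")
  q <- quantiles[names(fc1)]
  track <- smooth_over_intensity(abs(fc1 - fc2), q, span = span, ...)
  ord <- structure(data.frame(gene = names(fc1), min_quantile = q,
                              row.names = NULL, stringsAsFactors = FALSE),
                   class = c("intensity_rank", "data.frame"))
  corr <- rolling_correlation(fc1, fc2, ord, window = window, step = step,
                              spearman_ci = "none")
  list(track = track, correlation = corr)
}

#' Select low-intensity discordant genes
#'
#' Genes in the bottom \code{max_quantile} of intensity on both
#' platforms whose platform fold-change estimates disagree by at least
#' \code{min_gap} (defaults 0.2 and 1.0), sorted by decreasing gap --
#' the selection rule for the qPCR validation panel.
#'
#' @param deA,deB [de_table()] results for the two platforms.
#' @param ranks an \code{intensity_rank} from [min_quantile()].
#' @param max_quantile intensity quantile cutoff (both platforms).
#' @param min_gap minimum |fcA - fcB|.
#' @return data.frame: gene, fc_a, fc_b, gap, quantile_a, quantile_b.
#' @export
select_discordant_low <- function(deA, deB, ranks, max_quantile = 0.2,
                                  min_gap = 1.0) {
  shared <- Reduce(intersect, list(deA$gene, deB$gene, ranks$gene))
  fa <- setNames(deA$logfc, deA$gene)[shared]
  fb <- setNames(deB$logfc, deB$gene)[shared]
  qa <- setNames(ranks$quantile_a, ranks$gene)[shared]
  qb <- setNames(ranks$quantile_b, ranks$gene)[shared]
  gap <- abs(fa - fb)
  pick <- qa <= max_quantile & qb <= max_quantile & gap >= min_gap
  out <- data.frame(gene = shared, fc_a = as.numeric(fa),
                    fc_b = as.numeric(fb), gap = as.numeric(gap),
                    quantile_a = as.numeric(qa), quantile_b = as.numeric(qb),
                    stringsAsFactors = FALSE)[pick, ]
  out <- out[order(-out$gap), ]
  rownames(out) <- NULL
  out
}

#' Log2 fold changes from qPCR Ct replicates
#'
#' Each Ct is centred by the mean Ct over all assayed genes and
#' replicates of its biological replicate (the all-gene normalization
#' rule), and the per-gene log2(G/E) fold change is the mean centred Ct
#' of the E samples minus that of the G samples (one PCR cycle = one
#' log2 unit; lower Ct = more abundant).
#'
#' @param ct data.frame with columns gene, biological, condition, ct (as
#'   produced by [simulate_qpcr()]).
#' @param numerator condition label used as the fold-change numerator
#'   (default the first condition appearing in the table).
#' @return named per-gene log2 fold change vector.
#' @export
qpcr_logfc <- function(ct, numerator = NULL) {
  req <- c("gene", "biological", "condition", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  if (is.null(numerator)) numerator <- unique(ct$condition)[1]
  center <- stats::ave(ct$ct, ct$biological)
  cct <- ct$ct - center
  genes <- unique(ct$gene)
  cond_of_gene <- split(ct$condition, ct$gene)
  missing <- vapply(cond_of_gene, function(cc)
    length(unique(cc)) < 2, logical(1))
  if (any(missing))
    stop("gene(s) absent in one condition: ",
         paste(names(missing)[missing], collapse = ", "))
  mean_by <- tapply(cct, list(ct$gene, ct$condition == numerator), mean)
  fc <- mean_by[, "FALSE"] - mean_by[, "TRUE"]
  fc[genes]
}

#' Cross-technology validation against qPCR
#'
#' Pearson correlations (with two-sided p-values) of each platform's
#' fold-change estimates against the qPCR estimates over a shared gene
#' panel, plus the per-gene table for replicate-distribution comparisons.
#'
#' @param fc_qpcr,fc_A,fc_B named per-gene log2 fold changes (>= 3 shared
#'   genes).
#' @return list of class \code{validation_report}: \code{cor_a},
#'   \code{p_a}, \code{cor_b}, \code{p_b}, \code{n}, \code{table}.
#' @export
validation_report <- function(fc_qpcr, fc_A, fc_B) {
  shared <- Reduce(intersect, list(names(fc_qpcr), names(fc_A), names(fc_B)))
  if (length(shared) < 3) stop("need >= 3 shared genes")
  qv <- as.numeric(fc_qpcr[shared])
  av <- as.numeric(fc_A[shared]); bv <- as.numeric(fc_B[shared])
  ta <- stats::cor.test(av, qv)
  tb <- stats::cor.test(bv, qv)
  structure(list(cor_a = unname(ta$estimate), p_a = ta$p.value,
                 cor_b = unname(tb$estimate), p_b = tb$p.value,
                 n = length(shared),
                 table = data.frame(gene = shared, fc_qpcr = qv,
                                    fc_a = av, fc_b = bv,
                                    stringsAsFactors = FALSE)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("qPCR validation over", x$n, "genes:\n")
  cat(sprintf("  platform A vs qPCR: r = %.3f (p = %.3g)\n", x$cor_a, x$p_a))
  cat(sprintf("  platform B vs qPCR: r = %.3f (p = %.3g)\n", x$cor_b, x$p_b))
  invisible(x)
}
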
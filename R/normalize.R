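#' Pool counts to one column per biological replicate
#'
#' Counts are summed over the preparation and chip/lane replicates within
#' each biological replicate, yielding one library per biological
#' replicate (4 columns for the canonical design).  Technical replicates
#' at the later nested stages are not independent biological replicates;
#' treating them as such in differential expression would be
#' pseudoreplication that underestimates the within-group variation, so
#' the pooled matrix is the one used for testing, while the unpooled
#' 16-sample matrix is reserved for variance decomposition.
#'
#' @param counts an [expression_matrix()] with platform "counts".
#' @param design the matching [nested_design].
#' @return An [expression_matrix()] (platform "counts") with one column
#'   per biological replicate and a collapsed design in attribute
#'   \code{"design"}.
#' @export
pool_counts <- function(counts, design) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$platform != "counts")
    stop("pool_counts requires platform 'counts', got '",
         counts$platform, "'")
  .match_design(counts, design)
  groups <- .design_groups(design, "biological")
  pooled <- vapply(groups, function(idx)
    rowSums(counts$values[, idx, drop = FALSE]), numeric(nrow(counts$values)))
  attr_design <- .collapse_design(design)
  out <- expression_matrix(pooled, platform = "counts",
                           intensity = counts$intensity)
  attr(out, "design") <- attr_design
  out
}

#' Average array log-ratios to one column per biological replicate
#'
#' Arithmetic mean of the log2 ratios over all preparation and chip
#' replicates within each biological replicate.
#'
#' @param ratios an [expression_matrix()] with platform "logratio".
#' @param design the matching [nested_design].
#' @return An [expression_matrix()] (platform "logratio") with one column
#'   per biological replicate.
#' @export
average_array <- function(ratios, design) {
  stopifnot(inherits(ratios, "expression_matrix"))
  if (ratios$platform != "logratio")
    stop("average_array requires platform 'logratio', got '",
         ratios$platform, "'")
  .match_design(ratios, design)
  groups <- .design_groups(design, "biological")
  avg <- vapply(groups, function(idx)
    rowMeans(ratios$values[, idx, drop = FALSE]), numeric(nrow(ratios$values)))
  out <- expression_matrix(avg, platform = "logratio",
                           intensity = ratios$intensity)
  attr(out, "design") <- .collapse_design(design)
  out
}

.match_design <- function(x, design) {
  if (!identical(colnames(x$values), design$sample))
    stop("matrix samples do not match the design (order and names must agree)")
  invisible(TRUE)
}

# one row per biological replicate, keeping the condition label
.collapse_design <- function(design) {
  unique(design[, c("biological", "condition")])
}

#' Log2 counts per million
#'
#' \code{log2((count + prior) / (lib_size + 2 * prior) * 1e6)}, the
#' offset-stabilized log-CPM transform used before precision weighting.
#'
#' @param counts matrix (or [expression_matrix()]) of counts.
#' @param lib_sizes per-sample library sizes; default column sums.
#' @param prior prior count, default 0.5.
#' @return log2-CPM matrix.
#' @export
log_cpm <- function(counts, lib_sizes = NULL, prior = 0.5) {
  v <- if (inherits(counts, "expression_matrix")) counts$values else
    as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(v)
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  sweep(log2(v + prior), 2, log2((lib_sizes + 2 * prior) / 1e6), "-")
}

#' Log-CPM with voom precision weights
#'
#' Gene-wise linear models are fit to log2-CPM, a locally weighted
#' regression trend of sqrt(residual sd) against mean log2 count is
#' estimated, and each observation receives weight
#' predicted-sqrt-sd^(-4) at its fitted log-count (the voom procedure).
#' Weights are floored at \code{weight_floor}.
#'
#' @param counts matrix or [expression_matrix()] of counts.
#' @param design_model design matrix of sample covariates (e.g.
#'   \code{model.matrix(~ condition)}); must leave >= 2 residual df.
#' @param lib_sizes per-sample effective library sizes (library size times
#'   normalization factor); default column sums.
#' @param span lowess span for the mean-variance trend.
#' @param weight_floor positive lower bound on weights.
#' @return list of class \code{weighted_log_matrix} with elements
#'   \code{log2} (values), \code{weights}, \code{lib_sizes}.
#' @export
voom_weights <- function(counts, design_model, lib_sizes = NULL,
                         span = 0.5, weight_floor = 1e-6) {
  v <- if (inherits(counts, "expression_matrix")) counts$values else
    as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(v)
  if (ncol(v) - qr(design_model)$rank < 2)
    stop("voom_weights needs >= 2 residual degrees of freedom")
  fit <- limma::voom(v, design = design_model, lib.size = lib_sizes,
                     span = span)
  w <- pmax(fit$weights, weight_floor)
  dimnames(w) <- dimnames(fit$E)
  structure(list(log2 = fit$E, weights = w, lib_sizes = lib_sizes),
            class = "weighted_log_matrix")
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per sample versus a reference column, M and A
#' values over genes positive in both are doubly trimmed (30% on M, 5% on
#' A by default) and the factor is 2 to the precision-weighted mean of the
#' retained M values; factors are rescaled to geometric mean 1.
#'
#' @param counts matrix or [expression_matrix()] of counts.
#' @param ref_column reference sample index, or NULL for automatic choice
#'   (sample whose upper quartile is closest to the mean upper quartile).
#' @return named per-sample factor vector with geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_column = NULL) {
  v <- if (inherits(counts, "expression_matrix")) counts$values else
    as.matrix(counts)
  .check_norm_input(v)
  f <- edgeR::calcNormFactors(v, method = "TMM", refColumn = ref_column)
  setNames(as.numeric(f), colnames(v))
}

#' RLE (median-of-ratios) normalization factors
#'
#' Per sample, the median over genes positive in every sample of the
#' count divided by the gene's geometric mean across samples; rescaled to
#' geometric mean 1.  (Unlike TMM these factors absorb library size.)
#'
#' @param counts matrix or [expression_matrix()] of counts.
#' @return named per-sample factor vector with geometric mean 1.
#' @export
rle_factors <- function(counts) {
  v <- if (inherits(counts, "expression_matrix")) counts$values else
    as.matrix(counts)
  .check_norm_input(v)
  pos <- rowSums(v > 0) == ncol(v)
  if (!any(pos)) stop("no gene with all-positive counts")
  lg <- log(v[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  f <- apply(v[pos, , drop = FALSE], 2, function(col) median(col / geo))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(v))
}

.check_norm_input <- function(v) {
  zero <- colSums(v) <= 0
  if (any(zero))
    stop("column(s) with no counts: ",
         paste(colnames(v)[zero], collapse = ", "))
  invisible(TRUE)
}

#' Quantile normalization
#'
#' Each column's empirical distribution is replaced by the mean
#' order-statistic distribution; ties share the mean of the values they
#' would have received.
#'
#' @param x numeric matrix (no missing values).
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("quantile_normalize does not accept missing values")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Normalize a pooled count or array matrix
#'
#' Convenience front end used by the downstream stages: for counts,
#' computes scaling factors ("tmm", "rle" or "none") and returns log2-CPM
#' at effective library sizes, optionally with voom precision weights; for
#' arrays, optionally quantile-normalizes the log-ratio columns.
#'
#' @param x an [expression_matrix()].
#' @param method "tmm", "rle", "quantile" or "none".
#' @param design_model design matrix for [voom_weights()]; if NULL no
#'   weights are computed and plain log-CPM is returned for counts.
#' @return for counts, a \code{weighted_log_matrix} (weights all 1 when
#'   \code{design_model} is NULL); for arrays, a
#'   \code{weighted_log_matrix} with unit weights.
#' @export
normalize_matrix <- function(x, method = c("tmm", "rle", "quantile", "none"),
                             design_model = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expression_matrix"))
  if (x$platform == "counts") {
    lib <- colSums(x$values)
    eff <- switch(method,
      tmm  = lib * tmm_factors(x),
      rle  = {
        f <- rle_factors(x)
        # RLE factors already absorb library size up to scale
        f * exp(mean(log(lib)))
      },
      quantile = lib,
      none = lib)
    if (!is.null(design_model))
      return(voom_weights(x, design_model, lib_sizes = eff))
    lc <- log_cpm(x$values, lib_sizes = eff)
    if (method == "quantile") lc <- quantile_normalize(lc)
    structure(list(log2 = lc, weights = array(1, dim(lc), dimnames(lc)),
                   lib_sizes = eff),
              class = "weighted_log_matrix")
  } else {
    v <- x$values
    if (method == "quantile") v <- quantile_normalize(v)
    structure(list(log2 = v, weights = array(1, dim(v), dimnames(v)),
                   lib_sizes = rep(1, ncol(v))),
              class = "weighted_log_matrix")
  }
}
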
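#' Per-gene nested-ANOVA variance decomposition
#'
#' The central computation: for each gene's profile across the 16 nested
#' samples, three nested fixed-effects linear models are fit -- M1 with
#' condition means, M2 with biological-replicate means, M3 with
#' preparation means -- and the adjusted R-squared of each
#' (\code{adjR2 = 1 - (1 - R2) (n - 1) / (n - p)}) partitions the profile
#' variance into stage contributions:
#' condition = adjR2(M1); biological = adjR2(M2) - adjR2(M1);
#' preparation = adjR2(M3) - adjR2(M2); residual (chip/lane) =
#' 1 - adjR2(M3).  The chip/lane stage is deliberately left as residual
#' variation: parameterizing it would leave zero residual degrees of
#' freedom.  Negative components are clipped to zero and the vector
#' renormalized to sum to one.
#'
#' @name nested_r2
NULL

# adjusted R-squared from R-squared
.adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p)

# clip negatives, renormalize rows to sum 1 (NA rows pass through)
.clip_renorm <- function(m) {
  m[which(m < 0)] <- 0
  s <- rowSums(m)
  ok <- which(s > 0)
  m[ok, ] <- m[ok, , drop = FALSE] / s[ok]
  m
}

# per-level column-index matrices used by the vectorized fits
.level_indicators <- function(design) {
  lapply(c(condition = "condition", biological = "biological",
           preparation = "preparation"), function(lev) {
    f <- factor(design[[lev]], levels = unique(design[[lev]]))
    stats::model.matrix(~ 0 + f)
  })
}

# Gaussian nested decomposition for a gene x sample matrix.
# Returns list(frac = matrix, adj_r2 = matrix, r2 = matrix, degenerate)
.nested_r2_matrix <- function(Y, design, tol = 1e-12) {
  n <- ncol(Y)
  inds <- .level_indicators(design)
  tot <- rowSums(Y^2) - rowSums(Y)^2 / n
  degenerate <- tot <= tol * pmax(1, rowSums(Y^2))
  r2 <- vapply(inds, function(Z) {
    size <- colSums(Z)
    S <- Y %*% Z                      # per-group sums
    ssfit <- rowSums(sweep(S^2, 2, size, "/")) - rowSums(Y)^2 / n
    pmin(pmax(ssfit / ifelse(tot > 0, tot, NA_real_), 0), 1)
  }, numeric(nrow(Y)))
  if (nrow(Y) == 1) r2 <- matrix(r2, nrow = 1,
                                 dimnames = list(rownames(Y), names(inds)))
  p <- vapply(inds, ncol, integer(1))
  adj <- vapply(seq_along(inds), function(k) .adj_r2(r2[, k], n, p[k]),
                numeric(nrow(Y)))
  if (nrow(Y) == 1) adj <- matrix(adj, nrow = 1)
  frac <- cbind(condition   = adj[, 1],
                biological  = adj[, 2] - adj[, 1],
                preparation = adj[, 3] - adj[, 2],
                residual    = 1 - adj[, 3])
  frac <- .clip_renorm(frac)
  frac[degenerate, ] <- NA_real_
  rownames(frac) <- rownames(Y)
  list(frac = frac, adj_r2 = adj, r2 = r2, degenerate = degenerate)
}

#' @describeIn nested_r2 decompose one 16-value profile (Gaussian,
#'   adjusted R-squared).
#' @param y numeric vector of one gene's values, in design sample order.
#' @param design the matching [nested_design].
#' @return named fractions (condition, biological, preparation, residual)
#'   summing to 1, or all-NA for a degenerate (zero-variance) profile.
#' @export
nested_r2 <- function(y, design) {
  stopifnot(length(y) == nrow(design))
  Y <- matrix(as.numeric(y), nrow = 1,
              dimnames = list("y", design$sample))
  res <- .nested_r2_matrix(Y, design)
  if (res$degenerate[1])
    warning("degenerate profile: zero total variance")
  res$frac[1, ]
}

# Poisson deviance for observed y and fitted mu (0 log 0 = 0)
.pois_dev <- function(y, mu) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (t1 - (y - mu))
}

# deviance-R2 nested decomposition for count matrices.
# Each model's Poisson MLE with a log lib-size offset has the closed form
# rate = (group count sum) / (group lib-size sum).
.count_nested_r2_matrix <- function(Y, design, lib_sizes, tol = 1e-12) {
  n <- ncol(Y)
  inds <- .level_indicators(design)
  totc <- rowSums(Y)
  degenerate <- totc <= 0
  dev_for <- function(Z) {
    glib <- as.numeric(lib_sizes %*% Z)
    S <- Y %*% Z
    rate <- sweep(S, 2, glib, "/")
    mu <- rate %*% t(Z) * rep(lib_sizes, each = nrow(Y))
    rowSums(.pois_dev(Y, pmax(mu, 1e-300)))
  }
  d0 <- dev_for(matrix(1, n, 1))
  degenerate <- degenerate | d0 <= tol
  r2 <- vapply(inds, function(Z) {
    d <- dev_for(Z)
    pmin(pmax(1 - d / ifelse(d0 > tol, d0, NA_real_), 0), 1)
  }, numeric(nrow(Y)))
  if (nrow(Y) == 1) r2 <- matrix(r2, nrow = 1)
  p <- vapply(inds, ncol, integer(1))
  adj <- vapply(seq_along(inds), function(k) .adj_r2(r2[, k], n, p[k]),
                numeric(nrow(Y)))
  if (nrow(Y) == 1) adj <- matrix(adj, nrow = 1)
  frac <- cbind(condition   = adj[, 1],
                biological  = adj[, 2] - adj[, 1],
                preparation = adj[, 3] - adj[, 2],
                residual    = 1 - adj[, 3])
  frac <- .clip_renorm(frac)
  frac[degenerate, ] <- NA_real_
  rownames(frac) <- rownames(Y)
  list(frac = frac, adj_r2 = adj, r2 = r2, degenerate = degenerate)
}

#' @describeIn nested_r2 count-data variant: the same three nested models
#'   fit as Poisson log-linear models with a log library-size offset,
#'   using deviance R-squared (1 - model deviance / null deviance) with
#'   the same small-sample df adjustment.
#' @param counts nonnegative integer vector of one gene's counts.
#' @param lib_sizes per-sample library sizes (offsets).
#' @export
count_nested_r2 <- function(counts, design, lib_sizes) {
  stopifnot(length(counts) == nrow(design),
            length(lib_sizes) == nrow(design), all(lib_sizes > 0))
  Y <- matrix(as.numeric(counts), nrow = 1,
              dimnames = list("y", design$sample))
  res <- .count_nested_r2_matrix(Y, design, as.numeric(lib_sizes))
  if (res$degenerate[1])
    warning("degenerate profile: zero total count")
  res$frac[1, ]
}

#' Decompose every gene of an unpooled 16-sample matrix
#'
#' Applies [nested_r2()] (variant "gaussian") or [count_nested_r2()]
#' (variant "count") to each gene and attaches per-gene intensity
#' quantiles.  Degenerate (zero-variance or zero-count) genes are flagged
#' rather than aborting the matrix and are excluded from smoothing and
#' binning downstream; their number is reported by \code{print}.
#'
#' @param x an [expression_matrix()] (or a \code{weighted_log_matrix} from
#'   [normalize_matrix()] for variant "gaussian", in which case intensity
#'   must be supplied).
#' @param design the matching [nested_design].
#' @param variant "gaussian" (adjusted R-squared on log-scale values) or
#'   "count" (Poisson deviance R-squared on raw counts).
#' @param lib_sizes library sizes for variant "count"; default column
#'   sums.
#' @param intensity per-gene intensity overriding the matrix's own.
#' @return An object of class \code{nested_decomposition}: a data.frame
#'   with columns gene, fraction_condition, fraction_biological,
#'   fraction_preparation, fraction_residual, intensity,
#'   intensity_quantile, degenerate; attributes \code{platform} and
#'   \code{variant}.
#' @seealso [smooth_over_intensity()], [bin_platform_test()]
#' @export
decompose_matrix <- function(x, design, variant = c("gaussian", "count"),
                             lib_sizes = NULL, intensity = NULL) {
  variant <- match.arg(variant)
  if (inherits(x, "expression_matrix")) {
    Y <- x$values
    if (is.null(intensity)) intensity <- x$intensity
    platform <- x$platform
  } else if (inherits(x, "weighted_log_matrix")) {
    Y <- x$log2
    platform <- "logintensity"
    if (is.null(intensity))
      stop("intensity must be supplied for a weighted_log_matrix")
  } else {
    Y <- as.matrix(x)
    platform <- "logintensity"
    if (is.null(intensity)) stop("intensity must be supplied")
  }
  if (ncol(Y) != nrow(design))
    stop("matrix and design sample counts differ")
  res <- if (variant == "gaussian") {
    .nested_r2_matrix(Y, design)
  } else {
    if (any(Y < 0) || any(Y != round(Y)))
      stop("variant 'count' requires nonnegative integer values")
    if (is.null(lib_sizes)) lib_sizes <- colSums(Y)
    .count_nested_r2_matrix(Y, design, as.numeric(lib_sizes))
  }
  q <- rank(intensity, ties.method = "average") / length(intensity)
  out <- data.frame(gene = rownames(Y),
                    fraction_condition   = res$frac[, "condition"],
                    fraction_biological  = res$frac[, "biological"],
                    fraction_preparation = res$frac[, "preparation"],
                    fraction_residual    = res$frac[, "residual"],
                    intensity = as.numeric(intensity),
                    intensity_quantile = as.numeric(q),
                    degenerate = res$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("nested_decomposition", "data.frame"),
            platform = platform, variant = variant)
}

#' @export
print.nested_decomposition <- function(x, ...) {
  ok <- !x$degenerate
  cat("Nested variance decomposition (", attr(x, "variant"), " variant, ",
      "platform ", attr(x, "platform"), ")\n", sep = "")
  cat(nrow(x), "genes,", sum(!ok), "degenerate (excluded)\n")
  m <- colMeans(x[ok, c("fraction_condition", "fraction_biological",
                        "fraction_preparation", "fraction_residual")])
  cat("mean fractions: condition", sprintf("%.3f", m[1]),
      " biological", sprintf("%.3f", m[2]),
      " preparation", sprintf("%.3f", m[3]),
      " chip/lane", sprintf("%.3f", m[4]), "\n")
  invisible(x)
}

#' @export
summary.nested_decomposition <- function(object, ...) {
  ok <- !object$degenerate
  comps <- c("fraction_condition", "fraction_biological",
             "fraction_preparation", "fraction_residual")
  out <- t(vapply(comps, function(cc)
    c(mean = mean(object[[cc]][ok]),
      stats::quantile(object[[cc]][ok], c(0.25, 0.5, 0.75))),
    numeric(4)))
  structure(list(table = out, n = nrow(object), n_degenerate = sum(!ok),
                 variant = attr(object, "variant"),
                 platform = attr(object, "platform")),
            class = "summary.nested_decomposition")
}

#' @export
print.summary.nested_decomposition <- function(x, ...) {
  cat("Nested variance decomposition summary (", x$variant, ", ",
      x$platform, "): ", x$n, " genes, ", x$n_degenerate,
      " degenerate\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
plot.nested_decomposition <- function(x, span = 0.75, ...) {
  comps <- c(condition = "fraction_condition",
             biological = "fraction_biological",
             preparation = "fraction_preparation",
             `chip/lane` = "fraction_residual")
  cols <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a")
  ok <- !x$degenerate
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "intensity quantile",
                 ylab = "fraction of variance", ...)
  for (i in seq_along(comps)) {
    tr <- smooth_over_intensity(x[[comps[i]]][ok],
                                x$intensity_quantile[ok], span = span)
    graphics::lines(tr$quantile, tr$value, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", names(comps), col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Smooth per-gene values over intensity quantiles
#'
#' Locally weighted quadratic regression (LOESS) of a per-gene quantity
#' (a decomposition fraction, correlation, or |delta log-FC|) on the
#' intensity quantile, with a 95% confidence band from local standard
#' errors ("analytic") or a gene-resampling bootstrap ("bootstrap",
#' B = 200, seeded).
#'
#' @param values per-gene values.
#' @param quantiles per-gene intensity quantiles in (0, 1].
#' @param span LOESS span in (0, 1], default 0.75.
#' @param ci "analytic" or "bootstrap".
#' @param B bootstrap replicates.
#' @param grid_n number of grid points.
#' @param seed seed for the bootstrap.
#' @return data.frame of class \code{smoothed_track}: quantile, value,
#'   lower, upper.
#' @export
smooth_over_intensity <- function(values, quantiles, span = 0.75,
                                  ci = c("analytic", "bootstrap"), B = 200,
                                  grid_n = 101, seed = 1L) {
  ci <- match.arg(ci)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  keep <- is.finite(values) & is.finite(quantiles)
  values <- values[keep]; quantiles <- quantiles[keep]
  if (length(values) < 50)
    stop("smoothing needs >= 50 genes with finite values")
  grid <- seq(min(quantiles), max(quantiles), length.out = grid_n)
  df <- data.frame(values = values, quantiles = quantiles)
  fit <- stats::loess(values ~ quantiles, data = df, span = span,
                      degree = 2, surface = "direct")
  pred <- stats::predict(fit, newdata = data.frame(quantiles = grid),
                         se = TRUE)
  value <- as.numeric(pred$fit)
  if (ci == "analytic") {
    half <- 1.96 * as.numeric(pred$se.fit)
    lower <- value - half; upper <- value + half
  } else {
    set.seed(seed)
    n <- length(values)
    boots <- vapply(seq_len(B), function(b) {
      bdf <- df[sample.int(n, n, replace = TRUE), ]
      bf <- stats::loess(values ~ quantiles, data = bdf, span = span,
                         degree = 2, surface = "direct")
      as.numeric(stats::predict(bf, newdata = data.frame(quantiles = grid)))
    }, numeric(grid_n))
    lower <- apply(boots, 1, stats::quantile, 0.025, na.rm = TRUE)
    upper <- apply(boots, 1, stats::quantile, 0.975, na.rm = TRUE)
  }
  structure(data.frame(quantile = grid, value = value,
                       lower = pmin(lower, value),
                       upper = pmax(upper, value)),
            class = c("smoothed_track", "data.frame"))
}

#' Binned cross-platform comparison of residual fractions
#'
#' Genes (matched between two decomposition tables) are assigned to
#' equal-size bins by a shared intensity rank -- by default the
#' min-quantile rank if supplied, else table A's intensity quantile --
#' and within each bin a paired two-sided Wilcoxon signed-rank test
#' compares the per-gene chip/lane residual fractions of platform A
#' versus platform B.  Bins with fewer than 10 genes are flagged and not
#' tested.
#'
#' @param decompA,decompB [decompose_matrix()] results on the same genes.
#' @param n_bins number of equal-size intensity bins, default 10.
#' @param shared_quantile optional per-gene quantile (e.g. the
#'   min-quantile of [min_quantile()]) used for binning.
#' @param statistic "signed_rank" (paired, default) or "rank_sum"
#'   (unpaired).
#' @return data.frame: bin, n, median_diff (A - B), p, p_adj (BH across
#'   bins), tested.
#' @export
bin_platform_test <- function(decompA, decompB, n_bins = 10,
                              shared_quantile = NULL,
                              statistic = c("signed_rank", "rank_sum")) {
  statistic <- match.arg(statistic)
  if (!identical(decompA$gene, decompB$gene))
    stop("decomposition tables must cover the same genes in the same order")
  ok <- !decompA$degenerate & !decompB$degenerate
  a <- decompA$fraction_residual[ok]
  b <- decompB$fraction_residual[ok]
  q <- if (is.null(shared_quantile)) decompA$intensity_quantile[ok] else
    shared_quantile[ok]
  bin <- ceiling(rank(q, ties.method = "first") * n_bins / length(q))
  res <- lapply(seq_len(n_bins), function(k) {
    i <- bin == k
    n <- sum(i)
    if (n < 10)
      return(data.frame(bin = k, n = n, median_diff = NA_real_,
                        p = NA_real_, tested = FALSE))
    p <- if (statistic == "signed_rank") {
      d <- a[i] - b[i]
      if (all(d == 0)) 1 else
        stats::wilcox.test(a[i], b[i], paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::wilcox.test(a[i], b[i], exact = FALSE)$p.value
    }
    data.frame(bin = k, n = n, median_diff = stats::median(a[i] - b[i]),
               p = p, tested = TRUE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- stats::p.adjust(out$p[out$tested], "BH")
  out
}
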
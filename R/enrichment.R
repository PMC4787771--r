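#' Wilcoxon rank-sum gene-set test
#'
#' Two-sided Mann-Whitney test comparing the per-gene statistic of genes
#' inside a set against all genes outside it.  The exact null
#' distribution is used when the smaller group has at most
#' \code{exact_max} members and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param stat named per-gene statistic (log2 fold change, p-value, ...).
#' @param members gene ids in the set (at least 1, fewer than all genes).
#' @param exact_max largest min-group size for which the exact null is
#'   used.
#' @return list: p, direction (sign of in-set minus out-set median),
#'   effect (rank-biserial correlation), n_in, n_out, exact.
#' @export
wilcoxon_set_test <- function(stat, members, exact_max = 8) {
  if (is.null(names(stat))) stop("stat must be a named per-gene vector")
  inset <- names(stat) %in% members
  n_in <- sum(inset); n_out <- sum(!inset)
  if (n_in < 1 || n_out < 1)
    stop("set must contain between 1 and n-1 measured genes")
  x <- stat[inset]; y <- stat[!inset]
  ties <- anyDuplicated(stat) > 0
  exact <- min(n_in, n_out) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)          # Mann-Whitney U for x vs y
  effect <- 2 * u / (n_in * n_out) - 1
  list(p = wt$p.value,
       direction = sign(stats::median(x) - stats::median(y)),
       effect = effect, n_in = n_in, n_out = n_out, exact = exact)
}

#' Enrichment of all gene sets on a chosen ranking statistic
#'
#' Per set, a [wilcoxon_set_test()] of the chosen per-gene statistic:
#' signed log2 fold changes (\code{ranking = "logfc"}) or unsigned
#' differential-expression p-values (\code{ranking = "pvalue"}, smaller =
#' more extreme).  Set membership is intersected with the measured genes;
#' sets smaller than \code{min_size} after intersection are skipped.
#' BH adjustment is applied across tested sets.
#'
#' @param de a [de_table()] (or data.frame with gene, logfc, p columns).
#' @param sets a \code{gene_set_collection} (named list of gene ids).
#' @param ranking "logfc" or "pvalue".
#' @param min_size minimum set size after intersection, default 5.
#' @return data.frame of class \code{enrichment_table}: set, size,
#'   direction, effect, p, p_adj.
#' @export
enrich_all <- function(de, sets, ranking = c("logfc", "pvalue"),
                       min_size = 5) {
  ranking <- match.arg(ranking)
  stat <- switch(ranking,
                 logfc = setNames(de$logfc, de$gene),
                 pvalue = setNames(de$p, de$gene))
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(stat))
    if (length(members) < min_size || length(members) >= length(stat))
      return(NULL)
    res <- wilcoxon_set_test(stat, members)
    data.frame(set = nm, size = length(members),
               direction = res$direction, effect = res$effect,
               p = res$p, stringsAsFactors = FALSE)
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped))
    message("enrich_all: ", sum(skipped), " set(s) skipped (size < ",
            min_size, " after intersection)")
  out <- do.call(rbind, rows[!skipped])
  if (is.null(out))
    stop("no testable sets")
  out$p_adj <- stats::p.adjust(out$p, "BH")
  structure(out, class = c("enrichment_table", "data.frame"),
            ranking = ranking)
}

#' Assign gene sets to intensity bins
#'
#' Per set, the median min-quantile of its members (intersected with the
#' measured genes); sets are then binned into \code{n_bins} equal-count
#' bins of that median (bin 1 = lowest intensity).
#'
#' @param sets a \code{gene_set_collection}.
#' @param ranks an \code{intensity_rank} from [min_quantile()] (or any
#'   data.frame with gene and min_quantile).
#' @param n_bins number of bins, default 5.
#' @return data.frame: set, median_quantile, bin.
#' @export
set_intensity_bins <- function(sets, ranks, n_bins = 5) {
  q <- setNames(ranks$min_quantile, ranks$gene)
  med <- vapply(sets, function(members) {
    m <- intersect(members, names(q))
    if (!length(m)) NA_real_ else stats::median(q[m])
  }, numeric(1))
  ok <- !is.na(med)
  bin <- rep(NA_integer_, length(med))
  bin[ok] <- ceiling(rank(med[ok], ties.method = "first") * n_bins / sum(ok))
  data.frame(set = names(sets), median_quantile = as.numeric(med),
             bin = bin, stringsAsFactors = FALSE)
}

#' Per-bin enrichment p-value diagnostics
#'
#' For each intensity bin of gene sets, the histogram of enrichment
#' p-values (10 equal bins on [0, 1]) and a Kolmogorov-Smirnov uniformity
#' statistic.  Computed for each supplied result table (e.g. the logfc-
#' and pvalue-ranked enrichments of one platform) so the intensity
#' confounding of the p-value ranking is visible: under significance
#' ranking, low-intensity sets' genes occupy a narrow band of the
#' overall ranking and the enrichment p-values in the lowest bins depart
#' from uniformity, while fold-change ranking is far less affected.
#'
#' @param results named list of \code{enrichment_table}s (by ranking
#'   and/or platform).
#' @param bins a [set_intensity_bins()] table.
#' @return data.frame: ranking (list name), bin, n_sets, ks_stat, ks_p,
#'   and hist_01 ... hist_10 histogram counts.
#' @export
binwise_pvalue_diagnostic <- function(results, bins) {
  out <- lapply(names(results), function(nm) {
    tab <- results[[nm]]
    b <- bins$bin[match(tab$set, bins$set)]
    rows <- lapply(sort(unique(stats::na.omit(b))), function(k) {
      p <- tab$p[which(b == k)]
      ks <- suppressWarnings(stats::ks.test(p, "punif"))
      h <- graphics::hist(p, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
      cbind(data.frame(ranking = nm, bin = k, n_sets = length(p),
                       ks_stat = unname(ks$statistic),
                       ks_p = ks$p.value, stringsAsFactors = FALSE),
            as.data.frame(t(setNames(h, sprintf("hist_%02d", 1:10)))))
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
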
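#' Expression matrices
#'
#' A light container for a gene x sample matrix with a platform tag and a
#' per-gene intensity summary.  \code{platform} is one of \code{"counts"}
#' (nonnegative integer read counts), \code{"logratio"} (two-channel
#' log2(red/green) ratios) or \code{"logintensity"} (generic log-scale
#' values).  Intensity defaults to the row sum of counts (total reads per
#' gene) for \code{counts} and must be supplied for arrays (typically mean
#' cy5 fluorescence across samples).
#'
#' @param values numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param platform \code{"counts"}, \code{"logratio"} or
#'   \code{"logintensity"}.
#' @param intensity optional per-gene nonnegative intensity vector; default
#'   for counts is the row sum.
#' @return An object of class \code{expression_matrix}: a list with
#'   elements \code{values}, \code{platform}, \code{intensity}.
#' @export
expression_matrix <- function(values, platform = c("counts", "logratio",
                                                   "logintensity"),
                              intensity = NULL) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id(s): ",
         rownames(values)[duplicated(rownames(values))][1])
  if (anyNA(values)) stop("missing values are not permitted; pre-filter genes")
  if (platform == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("platform 'counts' requires nonnegative integer values")
    if (is.null(intensity)) intensity <- rowSums(values)
  }
  if (is.null(intensity))
    stop("intensity must be supplied for platform '", platform, "'")
  intensity <- as.numeric(intensity)
  if (length(intensity) != nrow(values))
    stop("intensity must have one value per gene")
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  names(intensity) <- rownames(values)
  structure(list(values = values, platform = platform, intensity = intensity),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples, platform =", x$platform, "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a gene x sample matrix from TSV
#'
#' First column gene ids, header row sample ids, tab-separated, no
#' quoting, '.' decimal separator; lines starting with '#' are skipped.
#' Counts are validated as nonnegative integers.
#'
#' @param path path to a TSV file.
#' @param platform platform tag, see [expression_matrix()].
#' @param intensity optional per-gene intensity vector (e.g. mean cy5
#'   fluorescence); by default counts use row sums.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, platform = c("counts", "logratio",
                                           "logintensity"),
                        intensity = NULL) {
  platform <- match.arg(platform)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a gene column plus >=1 sample")
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id '", genes[duplicated(genes)][1], "' in ", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", vals[idx[1], idx[2]], "' at gene '",
         genes[idx[1]], "', sample '", colnames(vals)[idx[2]], "'")
  }
  if (platform == "counts" && any(num != round(num) | num < 0)) {
    idx <- which(num != round(num) | num < 0, arr.ind = TRUE)[1, ]
    stop("count matrix has non-integer value '", vals[idx[1], idx[2]],
         "' at gene '", genes[idx[1]], "', sample '",
         colnames(vals)[idx[2]], "'")
  }
  dimnames(num) <- list(genes, colnames(vals))
  expression_matrix(num, platform = platform, intensity = intensity)
}

#' Write an expression matrix as TSV
#'
#' Values are written with full precision (15 significant digits) so reals
#' round-trip to at least 12 significant digits and integer counts
#' bit-exactly.
#'
#' @param x an [expression_matrix()] or a plain matrix.
#' @param path output path.
#' @param meta optional named character vector written as `# key: value`
#'   header lines (e.g. command, config hash, seed).
#' @export
write_matrix <- function(x, path, meta = NULL) {
  v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  .write_meta(con, meta)
  writeLines(paste(c("gene", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 2, function(col) formatC(col, digits = 15, format = "g"))
  writeLines(do.call(paste, c(list(rownames(v)), split(body, col(body)),
                              sep = "\t")), con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member gene
#' ids.  Duplicate members within a set are dropped with a warning; empty
#' sets and lines with fewer than three fields are errors.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of class
#'   \code{gene_set_collection}, with a \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene set name '", names_[duplicated(names_)][1], "'")
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    if (anyDuplicated(members)) {
      warning("set '", names_[i], "': dropping ",
              sum(duplicated(members)), " duplicate member(s)")
      members <- unique(members)
    }
    members
  })
  names(sets) <- names_
  names(desc) <- names_
  structure(sets, description = desc, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors (or a
#'   \code{gene_set_collection}).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
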
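#' Nested experimental designs
#'
#' A nested design maps each sample to its position in a balanced
#' hierarchy: condition (two levels, e.g. glucose vs ethanol), biological
#' replicate nested in condition, library/labelling preparation nested in
#' biological replicate, and chip or lane ("unit") replicate of each
#' preparation.  The canonical layout is 2 conditions x 2 biological
#' replicates x 2 preparations x 2 units = 16 samples, run identically on
#' both platforms.  Unit labels (e.g. \code{u1}, \code{u2}) identify the
#' physical chip or lane and are shared across preparations; all other
#' levels form a tree.
#'
#' @param samples data.frame with columns \code{sample}, \code{condition},
#'   \code{biological}, \code{preparation}, \code{unit} (character).
#' @param relaxed logical; if \code{TRUE}, any balanced design with a
#'   constant branching factor per level (a balanced 2^k-style layout,
#'   branching 1 or 2 at each stage) is accepted instead of requiring the
#'   strict 2/2/2/2 structure.
#' @return An object of class \code{nested_design}: the validated
#'   data.frame with attribute \code{relaxed}.
#' @seealso [read_design()], [canonical_design()]
#' @export
nested_design <- function(samples, relaxed = FALSE) {
  req <- c("sample", "condition", "biological", "preparation", "unit")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols))
    stop("design table lacks column(s): ", paste(missing_cols, collapse = ", "))
  d <- as.data.frame(lapply(samples[req], as.character),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample))
    stop("duplicate sample id(s): ",
         paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
  .check_tree(d)
  .check_balance(d, relaxed)
  structure(d, class = c("nested_design", "data.frame"), relaxed = relaxed)
}

# nesting must be a tree above the unit level: each child label maps to
# exactly one parent label
.check_tree <- function(d) {
  pairs <- list(c("biological", "condition"), c("preparation", "biological"))
  for (p in pairs) {
    child <- p[1]; parent <- p[2]
    map <- unique(d[, c(child, parent)])
    bad <- map[[child]][duplicated(map[[child]])]
    if (length(bad))
      stop("nesting violation: ", child, " '", bad[1],
           "' spans more than one ", parent)
  }
  invisible(TRUE)
}

.check_balance <- function(d, relaxed) {
  n_per <- function(child, parent) {
    tab <- tapply(d[[child]], d[[parent]], function(x) length(unique(x)))
    as.integer(tab)
  }
  branching <- list(
    condition   = length(unique(d$condition)),
    biological  = n_per("biological", "condition"),
    preparation = n_per("preparation", "biological"),
    unit        = as.integer(tapply(d$sample, d$preparation, length))
  )
  # units within a preparation must carry distinct unit labels
  u_distinct <- tapply(d$unit, d$preparation, function(x) anyDuplicated(x) == 0)
  if (!all(u_distinct))
    stop("unbalanced design at level 'unit': preparation '",
         names(u_distinct)[!u_distinct][1], "' repeats a unit label")
  if (branching$condition != 2)
    stop("unbalanced design at level 'condition': expected 2 levels, found ",
         branching$condition)
  for (lev in c("biological", "preparation", "unit")) {
    b <- branching[[lev]]
    if (length(unique(b)) != 1)
      stop("unbalanced design at level '", lev,
           "': branching factors differ (",
           paste(b, collapse = ","), ")")
    if (!relaxed && b[1] != 2)
      stop("unbalanced design at level '", lev, "': expected 2 per parent, found ",
           b[1], " (use relaxed = TRUE for other balanced layouts)")
  }
  invisible(TRUE)
}

#' @export
print.nested_design <- function(x, ...) {
  cat("Nested design:", nrow(x), "samples,",
      length(unique(x$condition)), "conditions x",
      length(unique(x$biological)), "biological x",
      length(unique(x$preparation)), "preparations\n")
  NextMethod()
}

#' The canonical 16-sample nested design
#'
#' Two conditions (\code{G}, \code{E}), two biological replicates each,
#' two preparations per biological replicate, each preparation run once on
#' each of two units (chips or lanes).
#'
#' @param conditions two condition labels, default \code{c("G","E")}.
#' @return A [nested_design] with 16 rows.
#' @export
canonical_design <- function(conditions = c("G", "E")) {
  stopifnot(length(conditions) == 2)
  rows <- expand.grid(unit = c("u1", "u2"), prep = 1:2, bio = 1:2,
                      condition = conditions, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  bio  <- paste0(rows$condition, rows$bio)
  prep <- paste0(bio, "p", rows$prep)
  nested_design(data.frame(
    sample      = paste0(prep, rows$unit),
    condition   = rows$condition,
    biological  = bio,
    preparation = prep,
    unit        = rows$unit,
    stringsAsFactors = FALSE
  ))
}

#' Read a nested design table
#'
#' Tab-separated, UTF-8, columns \code{sample}, \code{condition},
#' \code{biological}, \code{preparation}, \code{unit}; lines starting with
#' \code{#} are metadata and skipped.
#'
#' @inheritParams nested_design
#' @param path path to a TSV file.
#' @return A [nested_design].
#' @export
read_design <- function(path, relaxed = FALSE) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         colClasses = "character", check.names = FALSE)
  nested_design(d, relaxed = relaxed)
}

#' Write a design table as TSV
#'
#' @param design a [nested_design].
#' @param path output path.
#' @param meta optional named character vector written as `# key: value`
#'   header lines.
#' @export
write_design <- function(design, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  .write_meta(con, meta)
  utils::write.table(as.data.frame(design), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_meta <- function(con, meta) {
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
}

# index helpers: list of sample indices per level of a factor, in design order
.design_groups <- function(design, level) {
  f <- design[[level]]
  split(seq_len(nrow(design)), factor(f, levels = unique(f)))
}

# condition indicator (1 for the first condition in design order, treated
# as the "G" numerator condition unless numerator is given)
.condition_indicator <- function(design, numerator = NULL) {
  lev <- unique(design$condition)
  if (is.null(numerator)) numerator <- lev[1]
  if (!numerator %in% lev) stop("condition '", numerator, "' not in design")
  as.numeric(design$condition == numerator)
}
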
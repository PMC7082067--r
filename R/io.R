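#' Rate tables
#'
#' A rate table holds piecewise-constant pairwise coalescence rate estimates
#' on a discretized time axis: columns \code{time_index} (0-based,
#' consecutive), \code{left_time_boundary}, \code{right_time_boundary}
#' (mutation-scaled; contiguous; the last right boundary may be \code{Inf})
#' and either one rate column \code{lambda} (a single-population run) or
#' three columns \code{lambda_00}, \code{lambda_01}, \code{lambda_11}
#' (within population 1, across, within population 2). Rates are
#' nonnegative; a cross rate of exactly zero encodes complete isolation.
#'
#' @param left,right segment boundaries, mutation-scaled.
#' @param lambdas numeric vector (single rate) or 3-column matrix/data.frame
#'   (within-1, cross, within-2).
#' @return a \code{data.frame} of class \code{rate_table}.
#' @export
rate_table <- function(left, right, lambdas) {
  if (is.null(dim(lambdas))) lambdas <- matrix(lambdas, ncol = 1L)
  lambdas <- as.matrix(lambdas)
  n <- length(left)
  if (length(right) != n || nrow(lambdas) != n)
    stop("left, right and lambdas must have matching lengths")
  if (!ncol(lambdas) %in% c(1L, 3L))
    stop("lambdas must have 1 or 3 columns")
  if (any(!is.finite(left)) || any(left < 0))
    stop("left boundaries must be finite and nonnegative")
  if (any(diff(left) <= 0)) stop("left boundaries must be strictly increasing")
  if (n > 1L && any(abs(utils::head(right, -1L) - left[-1L]) >
                    1e-12 * pmax(1, left[-1L])))
    stop("boundaries are not contiguous: left[i+1] must equal right[i]")
  if (any(lambdas < 0, na.rm = TRUE)) stop("rates must be nonnegative")
  cols <- if (ncol(lambdas) == 1L) "lambda" else
    c("lambda_00", "lambda_01", "lambda_11")
  df <- data.frame(time_index = 0:(n - 1L),
                   left_time_boundary = as.numeric(left),
                   right_time_boundary = as.numeric(right))
  for (j in seq_along(cols)) df[[cols[j]]] <- as.numeric(lambdas[, j])
  class(df) <- c("rate_table", "data.frame")
  df
}

lambda_columns <- function(tab) {
  grep("^lambda", names(tab), value = TRUE)
}

is_cross_table <- function(tab) length(lambda_columns(tab)) == 3L

#' Read a rate table
#'
#' Reads the tab-separated "final" dialect (header
#' \code{time_index left_time_boundary right_time_boundary lambda}) or the
#' combined three-rate dialect (\code{... lambda_00 lambda_01 lambda_11}).
#'
#' @param path file path.
#' @return a \code{rate_table}.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("time_index", "left_time_boundary", "right_time_boundary")
  if (!all(need %in% names(df)))
    stop("missing required columns in ", path)
  lcols <- grep("^lambda", names(df), value = TRUE)
  if (!length(lcols) %in% c(1L, 3L))
    stop("expected 1 or 3 lambda columns in ", path)
  for (cn in c(need, lcols)) {
    if (!is.numeric(df[[cn]]) && !all(df[[cn]] %in% c("Inf", "inf")))
      stop(sprintf("non-numeric values in column %s of %s (first bad line %d)",
                   cn, path,
                   which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1L] + 1L))
    df[[cn]] <- suppressWarnings(as.numeric(sub("^inf$", "Inf", df[[cn]])))
  }
  if (!identical(as.integer(df$time_index), seq_len(nrow(df)) - 1L))
    stop("time_index must be consecutive from 0 in ", path)
  bad <- which(abs(utils::head(df$right_time_boundary, -1L) -
                   df$left_time_boundary[-1L]) >
               1e-9 * pmax(1, df$left_time_boundary[-1L]))
  if (length(bad))
    stop(sprintf("non-contiguous boundaries in %s at line %d", path, bad[1L] + 2L))
  rate_table(df$left_time_boundary, df$right_time_boundary,
             as.matrix(df[lcols]))
}

#' Write a rate table
#'
#' Output is byte-stable for a fixed table: numbers are written with
#' \code{\%.14g}, tab-separated, with the standard header.
#'
#' @param table a \code{rate_table}.
#' @param path file path.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  cols <- names(table)
  lines <- paste(cols, collapse = "\t")
  body <- apply(table, 1L, function(r) {
    paste(c(sprintf("%d", as.integer(r[[1L]])),
            sprintf("%.14g", as.numeric(r[-1L]))), collapse = "\t")
  })
  writeLines(c(lines, body), path)
  invisible(path)
}

# piecewise-constant evaluation of a single-rate table at times t
# (values taken from the segment whose [left, right) interval covers t)
eval_rate_table <- function(tab, t, column = "lambda") {
  idx <- findInterval(t, tab$left_time_boundary)
  if (any(idx < 1L)) stop("evaluation time before table support")
  tab[[column]][idx]
}

#' Combine three single-rate runs into one cross-coalescence table
#'
#' Cross-population fitting needs the three rates lambda_00 (within
#' population 1), lambda_01 (across) and lambda_11 (within population 2) on
#' a common time axis. The combined table lives on the grid of the
#' across-population run; within-population rates are transferred by
#' piecewise-constant evaluation at the midpoints of the target segments
#' (for the open final segment, at its left boundary), which is exact
#' whenever the grids nest.
#'
#' @param within1,within2 single-rate tables for the two populations.
#' @param across single-rate table for cross-population pairs.
#' @return a three-rate \code{rate_table} on the grid of \code{across}.
#' @export
combine_cross_coal <- function(within1, across, within2) {
  for (tb in list(within1, across, within2)) {
    stopifnot(inherits(tb, "rate_table"))
    if (is_cross_table(tb)) stop("inputs must be single-rate tables")
  }
  lo <- max(within1$left_time_boundary[1L], within2$left_time_boundary[1L])
  hi <- min(utils::tail(within1$right_time_boundary, 1L),
            utils::tail(within2$right_time_boundary, 1L))
  if (across$left_time_boundary[1L] >= hi ||
      utils::tail(across$right_time_boundary, 1L) <= lo)
    stop("disjoint time supports between within and across tables")
  mid <- ifelse(is.finite(across$right_time_boundary),
                (across$left_time_boundary + across$right_time_boundary) / 2,
                across$left_time_boundary)
  # clamp midpoints into each source support before evaluation
  clamp_eval <- function(tab, t) {
    t <- pmax(t, tab$left_time_boundary[1L])
    eval_rate_table(tab, t)
  }
  rate_table(across$left_time_boundary, across$right_time_boundary,
             cbind(clamp_eval(within1, mid),
                   across$lambda,
                   clamp_eval(within2, mid)))
}

#' Read a multihetsep genotype file
#'
#' The multihetsep format is a headerless tab-separated table of segregating
#' sites: chromosome label, 1-based position, number of called sites since
#' the previous record (inclusive of the site itself), and the phased allele
#' string across haplotypes. Phase-ambiguous sites list the alternative
#' phasings comma-separated.
#'
#' @param path file path.
#' @return a \code{data.frame} of class \code{multihetsep} with columns
#'   \code{chrom}, \code{pos}, \code{called}, \code{alleles}.
#' @export
read_multihetsep <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "called", "alleles"),
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch, " in ", path)
  }
  nh <- nchar(sub(",.*$", "", df$alleles))
  if (length(unique(nh)) > 1L)
    stop("inconsistent haplotype counts in ", path)
  if (any(df$called <= 0L)) stop("called-sites counts must be positive")
  class(df) <- c("multihetsep", "data.frame")
  df
}

#' Write a multihetsep genotype file
#'
#' @param records a \code{multihetsep} data frame (or compatible).
#' @param path file path.
#' @export
write_multihetsep <- function(records, path) {
  stopifnot(all(c("chrom", "pos", "called", "alleles") %in% names(records)))
  writeLines(sprintf("%s\t%d\t%d\t%s", records$chrom, records$pos,
                     records$called, records$alleles), path)
  invisible(path)
}

# number of haplotypes in a multihetsep table
n_haplotypes <- function(records) {
  if (nrow(records) == 0L) return(0L)
  nchar(sub(",.*$", "", records$alleles[1L]))
}
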
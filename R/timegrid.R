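#' Parse a segment-pattern string
#'
#' Time discretization in the pairwise coalescent HMM and in the
#' isolation-migration fit uses a set of atomic time intervals grouped into
#' parameter segments. The grouping is written in the conventional pattern
#' syntax \code{"count*width+count*width+..."}: each term contributes
#' \code{count} parameter segments spanning \code{width} atomic intervals
#' each. The default used throughout is \code{"1*2+25*1+1*2+1*3"}: 28
#' parameter segments over 32 atomic intervals.
#'
#' @param pattern_text pattern string, e.g. \code{"1*2+25*1+1*2+1*3"}.
#' @return an object of class \code{time_pattern} with elements
#'   \code{groups} (two-column integer matrix: count, width),
#'   \code{n_segments} and \code{n_atomic}.
#' @examples
#' p <- parse_time_pattern("1*2+25*1+1*2+1*3")
#' p$n_segments  # 28
#' p$n_atomic    # 32
#' @export
parse_time_pattern <- function(pattern_text) {
  if (!is.character(pattern_text) || length(pattern_text) != 1L || is.na(pattern_text))
    stop("pattern must be a single string")
  terms <- strsplit(pattern_text, "+", fixed = TRUE)[[1L]]
  if (length(terms) == 0L) stop("empty pattern string")
  groups <- matrix(0L, nrow = length(terms), ncol = 2L,
                   dimnames = list(NULL, c("count", "width")))
  for (i in seq_along(terms)) {
    tok <- terms[[i]]
    if (!grepl("^[0-9]+\\*[0-9]+$", tok))
      stop(sprintf("malformed pattern term '%s' (expected count*width)", tok))
    cw <- as.integer(strsplit(tok, "*", fixed = TRUE)[[1L]])
    if (any(cw <= 0L))
      stop(sprintf("pattern term '%s' has zero or negative entries", tok))
    groups[i, ] <- cw
  }
  n_atomic <- sum(groups[, "count"] * groups[, "width"])
  if (n_atomic < 2L) stop("pattern must span at least 2 atomic intervals")
  structure(
    list(groups = groups,
         n_segments = sum(groups[, "count"]),
         n_atomic = n_atomic,
         text = pattern_text),
    class = "time_pattern")
}

#' @export
format.time_pattern <- function(x, ...) {
  paste(sprintf("%d*%d", x$groups[, "count"], x$groups[, "width"]),
        collapse = "+")
}

#' @export
print.time_pattern <- function(x, ...) {
  cat("time pattern ", format(x), ": ", x$n_segments, " segments over ",
      x$n_atomic, " atomic intervals\n", sep = "")
  invisible(x)
}

#' Map atomic intervals to parameter segments
#'
#' @param pattern a \code{time_pattern}.
#' @return integer vector of length \code{n_atomic}; entry i gives the
#'   (1-based) parameter segment of atomic interval i.
#' @export
segment_of_atomic <- function(pattern) {
  stopifnot(inherits(pattern, "time_pattern"))
  rep(seq_len(pattern$n_segments),
      rep(pattern$groups[, "width"], pattern$groups[, "count"]))
}

#' Build the discretized time axis
#'
#' Atomic interval boundaries are placed at exponential quantiles of the
#' pairwise-coalescence prior, the convention of the PSMC family: boundary i
#' (of n atomic intervals) sits at \eqn{-\log(1 - i/n)} in coalescent units,
#' divided by the number of haplotype pairs analysed jointly, and converted
#' to mutation-scaled units via \eqn{2 N_{ref} \mu}. The final interval is
#' open-ended. The grid is fully determined by its arguments.
#'
#' @param pattern a \code{time_pattern} or a pattern string.
#' @param n_haplotype_pairs number of haplotype pairs whose first coalescence
#'   the prior describes (default 1, the single-pair prior).
#' @param mu mutation rate per bp per generation (default 1.25e-8).
#' @param N_ref reference diploid size fixing the coalescent-to-generation
#'   scale of the boundaries (default 20,000).
#' @param spacing \code{"quantile"} (default) for exponential-quantile
#'   boundaries, or \code{"log"} for geometrically spaced boundaries
#'   between \code{t_min} and \code{t_max} (coalescent units of 2 N_ref
#'   generations). The log spacing covers more decades -- roughly 3 kya to
#'   4 Myr at the defaults -- and is used for analyses that must resolve
#'   both a recent migration window and deep structure on one grid.
#' @param t_min,t_max span of the log spacing, in coalescent units.
#' @return an object of class \code{time_grid}: list with
#'   \code{boundaries_scaled} (length n_atomic, left boundaries, first = 0,
#'   in mutation-scaled units, i.e. generations times \code{mu}),
#'   \code{segment_of_atomic}, \code{pattern}, \code{mu}, and the derived
#'   left boundaries per parameter segment.
#' @export
make_time_grid <- function(pattern, n_haplotype_pairs = 1L, mu = 1.25e-8,
                           N_ref = 20000, spacing = c("quantile", "log"),
                           t_min = 0.0025, t_max = 3.5) {
  if (is.character(pattern)) pattern <- parse_time_pattern(pattern)
  stopifnot(inherits(pattern, "time_pattern"))
  spacing <- match.arg(spacing)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (n_haplotype_pairs < 1) stop("n_haplotype_pairs must be >= 1")
  n <- pattern$n_atomic
  # left boundaries of the n atomic intervals; the n-th interval is open
  q <- if (spacing == "quantile") {
    -log(1 - (0:(n - 1L)) / n) / n_haplotype_pairs
  } else {
    c(0, t_min * (t_max / t_min)^((0:(n - 2L)) / (n - 2L))) /
      n_haplotype_pairs
  }
  boundaries <- q * 2 * N_ref * mu
  seg <- segment_of_atomic(pattern)
  structure(
    list(boundaries_scaled = boundaries,
         segment_of_atomic = seg,
         segment_left_scaled = boundaries[!duplicated(seg)],
         pattern = pattern,
         n_segments = pattern$n_segments,
         n_atomic = n,
         mu = mu,
         N_ref = N_ref,
         n_haplotype_pairs = as.integer(n_haplotype_pairs)),
    class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("time grid: ", x$n_atomic, " atomic intervals / ", x$n_segments,
      " segments (pattern ", format(x$pattern), ")\n", sep = "")
  cat("  boundaries (generations): ",
      paste(signif(utils::head(x$boundaries_scaled, 3) / x$mu, 3), collapse = ", "),
      ", ..., ", signif(utils::tail(x$boundaries_scaled, 1) / x$mu, 3),
      "\n", sep = "")
  invisible(x)
}

#' Convert mutation-scaled times to generations (and back)
#'
#' Rate tables carry time in mutation-scaled units (expected mutations per
#' bp); dividing by the per-generation mutation rate gives generations.
#'
#' @param t_scaled time in mutation-scaled units.
#' @param mu mutation rate per bp per generation.
#' @return time in generations.
#' @export
scale_to_generations <- function(t_scaled, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("mu must be > 0")
  t_scaled / mu
}

#' @rdname scale_to_generations
#' @param t_gen time in generations.
#' @export
generations_to_scale <- function(t_gen, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("mu must be > 0")
  t_gen * mu
}

#' Convert generations to years
#'
#' All internal computation is in generations; conversion to years uses a
#' configurable generation time (default 29 years), applied only at the
#' reporting layer.
#'
#' @param t_gen time in generations.
#' @param gen_time years per generation.
#' @return time in years.
#' @export
generations_to_years <- function(t_gen, gen_time = 29) t_gen * gen_time

#' @rdname generations_to_years
#' @param t_years time in years.
#' @export
years_to_generations <- function(t_years, gen_time = 29) t_years / gen_time

#' Left boundaries of the parameter segments, in generations
#' @param grid a \code{time_grid}.
#' @return numeric vector of length \code{n_segments}.
#' @export
segment_boundaries_gen <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$segment_left_scaled / grid$mu
}

# widths (generations) of the parameter segments; the open-ended final
# segment is assigned the span of the last finite boundary interval
segment_widths_gen <- function(grid) {
  b <- segment_boundaries_gen(grid)
  K <- length(b)
  w <- diff(b)
  c(w, w[K - 1L])
}
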
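as_im_params <- function(x) {
  if (inherits(x, "im_fit")) x$params
  else if (inherits(x, "im_params")) x
  else stop("expected an im_fit or im_params object")
}

#' Times at which M(t) reaches given levels
#'
#' Returns, for each level, the first time the cumulative migration
#' probability reaches it. Within a segment the crossing is located by
#' linear interpolation on the -log(1 - M) scale, which is exact for a
#' piecewise-constant migration rate. Levels beyond the maximum attained M
#' are reported as \code{Inf} (unattained).
#'
#' @param fit an \code{im_fit} or \code{im_params}.
#' @param levels probabilities in (0, 1).
#' @return times in generations, one per level.
#' @export
m_percentiles <- function(fit, levels = c(0.01, 0.25, 0.5, 0.75, 0.99)) {
  if (any(levels <= 0 | levels >= 1)) stop("levels must be in (0, 1)")
  params <- as_im_params(fit)
  b <- params_boundaries_gen(params)
  K <- length(b)
  last_inc <- if (params$m[K] > 0) Inf else 0
  cum <- c(0, cumsum(params$m * c(diff(b), last_inc)))  # -log(1-M) at knots
  vapply(levels, function(lv) {
    target <- -log(1 - lv)
    i <- findInterval(target, cum, left.open = TRUE)  # segment index
    if (i > K || target > cum[K + 1L]) return(Inf)
    if (params$m[i] == 0) return(b[i])  # level attained exactly at the knot
    b[i] + (target - cum[i]) / params$m[i]
  }, numeric(1L))
}

#' Deep-ancestry fractions 1 - M(t*)
#'
#' The fraction of cross-population ancestry contributed by lineages that
#' had not yet merged at each requested time, read off the cumulative
#' migration probability.
#'
#' @param fit an \code{im_fit} or \code{im_params}.
#' @param t_stars_gen time points in generations.
#' @return fractions in [0, 1].
#' @export
deep_ancestry_fraction <- function(fit, t_stars_gen) {
  params <- as_im_params(fit)
  if (any(t_stars_gen < 0)) stop("time points must be >= 0")
  1 - cumulative_migration(params, t_stars_gen)
}

#' Detect migration pulses
#'
#' Partitions the time axis into pulses (contiguous runs of segments whose
#' per-segment M increment is above a floor) separated by plateaus. Floors
#' default to 1 percent of the largest per-segment increment of
#' -log(1 - M). Each pulse reports its time span, its increment of M, and
#' an M-increment-weighted mean time.
#'
#' @param fit an \code{im_fit} or \code{im_params}.
#' @param floor_frac pulse floor as a fraction of the maximum per-segment
#'   increment (default 0.01).
#' @return data.frame with one row per pulse: \code{start_gen},
#'   \code{end_gen}, \code{mean_gen} (weighted by M increment),
#'   \code{delta_M} (increment of M over the pulse).
#' @export
detect_pulses <- function(fit, floor_frac = 0.01) {
  params <- as_im_params(fit)
  b <- params_boundaries_gen(params)
  K <- length(b)
  w <- segment_widths_gen(params$grid)
  inc <- params$m * w  # per-segment increment of -log(1 - M)
  if (all(inc == 0))
    return(data.frame(start_gen = numeric(0), end_gen = numeric(0),
                      mean_gen = numeric(0), delta_M = numeric(0)))
  floor_inc <- floor_frac * max(inc)
  active <- inc > floor_inc
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  Mknots <- cumulative_migration(params)  # at left boundaries
  Mright <- c(Mknots[-1L], 1 - (1 - Mknots[K]) * exp(-inc[K]))
  out <- lapply(keep, function(r) {
    i0 <- starts[r]; i1 <- ends[r]
    segs <- i0:i1
    wts <- inc[segs]
    mid <- b[segs] + w[segs] / 2
    data.frame(start_gen = b[i0],
               end_gen = if (i1 < K) b[i1 + 1L] else b[K] + w[K],
               mean_gen = sum(mid * wts) / sum(wts),
               delta_M = Mright[i1] - Mknots[i0])
  })
  do.call(rbind, out)
}
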
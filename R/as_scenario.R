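#' Convert a fitted isolation-migration model into a scenario
#'
#' Builds a two-deme scenario whose piecewise sizes equal the fitted N1(t),
#' N2(t) and whose continuous symmetric migration rate equals the fitted
#' m(t) segment by segment, enabling the internal-consistency loop:
#' simulate (or compute exact rates) under a fitted model and refit.
#' Migration on the open-ended final segment is truncated at one extra
#' final-segment span.
#'
#' @param fit an \code{im_fit} or \code{im_params}.
#' @param haplotypes_per_deme haplotypes sampled per deme.
#' @param chrom_length_bp,n_chrom sequence simulation dimensions.
#' @param m_floor migration rates below this floor are dropped (they would
#'   create numerically idle migration windows); default 1e-10.
#' @return a \code{scenario_spec}.
#' @export
as_scenario <- function(fit, haplotypes_per_deme = 4L,
                        chrom_length_bp = 1e8, n_chrom = 22L,
                        m_floor = 1e-10) {
  params <- as_im_params(fit)
  b <- params_boundaries_gen(params)
  K <- length(b)
  w <- segment_widths_gen(params$grid)
  right <- c(b[-1L], b[K] + w[K])
  events <- list()
  for (i in seq_len(K)) {
    if (params$m[i] > m_floor)
      events[[length(events) + 1L]] <-
        list(type = "migration", start_gen = b[i], end_gen = right[i],
             demes = c("pop1", "pop2"), rate = params$m[i])
  }
  epochs <- function(N) {
    keep <- c(TRUE, diff(N) != 0)
    data.frame(start_gen = b[keep], N = N[keep])
  }
  mu <- params$grid$mu
  scenario_spec(
    demes = list(pop1 = epochs(pmin(params$N1, 1e7)),
                 pop2 = epochs(pmin(params$N2, 1e7))),
    events = events,
    samples = c(pop1 = haplotypes_per_deme, pop2 = haplotypes_per_deme),
    mu = mu,
    chrom_length_bp = chrom_length_bp, n_chrom = n_chrom)
}
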
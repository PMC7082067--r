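#' @export
print.im_fit <- function(x, ...) {
  K <- x$params$grid$n_segments
  cat("Isolation-migration fit over", K, "time segments\n")
  cat("  chi-square:", format(x$chi2, digits = 6),
      "(initial", format(x$chi2_init, digits = 6), ")\n")
  cat("  status:", x$status, "\n")
  med <- m_percentiles(x, 0.5)
  if (is.finite(med))
    cat("  M(t) median:", round(generations_to_years(med, x$gen_time)),
        "years\n")
  invisible(x)
}

#' Summarize an isolation-migration fit
#'
#' Reports the chi-square at the optimum, the migration-probability
#' percentiles, detected migration pulses and deep-ancestry fractions.
#'
#' @param object an \code{im_fit}.
#' @param percentiles levels of M(t) to locate (default 1, 25, 50, 75, 99
#'   percent).
#' @param deep_at_years time points (years) at which to report 1 - M(t).
#' @param ... unused.
#' @export
summary.im_fit <- function(object,
                           percentiles = c(0.01, 0.25, 0.5, 0.75, 0.99),
                           deep_at_years = c(3e5, 6e5, 8e5, 1e6), ...) {
  pc <- m_percentiles(object, percentiles)
  deep <- deep_ancestry_fraction(
    object, years_to_generations(deep_at_years, object$gen_time))
  out <- list(fit = object,
              percentiles_years = stats::setNames(
                generations_to_years(pc, object$gen_time),
                paste0(100 * percentiles, "%")),
              pulses = detect_pulses(object),
              deep_ancestry = stats::setNames(deep,
                                              paste0(deep_at_years / 1e3, "kya")))
  class(out) <- "summary.im_fit"
  out
}

#' @export
print.summary.im_fit <- function(x, ...) {
  print(x$fit)
  cat("\nM(t) percentiles (years):\n")
  print(round(x$percentiles_years))
  cat("\nmigration pulses:\n")
  print(x$pulses, digits = 4)
  cat("\ndeep-ancestry fractions 1 - M(t):\n")
  print(signif(x$deep_ancestry, 3))
  invisible(x)
}

#' Fitted parameters as a matrix
#'
#' @param object an \code{im_fit}.
#' @param ... unused.
#' @return matrix with one row per segment, columns N1, N2, m.
#' @export
coef.im_fit <- function(object, ...) {
  cbind(N1 = object$params$N1, N2 = object$params$N2, m = object$params$m)
}

#' Model predictions from a fit
#'
#' @param object an \code{im_fit}.
#' @param times_gen evaluation times in generations (defaults to the
#'   segment left boundaries).
#' @param type \code{"M"} for the cumulative migration probability,
#'   \code{"density"} or \code{"survival"} for the coalescence-time
#'   distribution of start state \code{s0}, or \code{"rates"} for the
#'   implied piecewise coalescence rates (ignores \code{times_gen}).
#' @param s0 start state for density/survival predictions.
#' @param ... unused.
#' @export
predict.im_fit <- function(object, times_gen = NULL,
                           type = c("M", "density", "survival", "rates"),
                           s0 = "S12", ...) {
  type <- match.arg(type)
  if (is.null(times_gen)) times_gen <- params_boundaries_gen(object$params)
  switch(type,
         M = cumulative_migration(object$params, times_gen),
         density = im_density(object$params, s0, times_gen),
         survival = im_survival(object$params, s0, times_gen),
         rates = im_implied_coalrates(object$params))
}

#' @export
fitted.im_fit <- function(object, ...) im_implied_coalrates(object$params)

#' Scaled residuals of the fit
#'
#' (P_IM - P_MSMC) / sqrt(P_MSMC) per time segment and start state, where
#' P denotes the per-segment coalescence probability mass; terms skipped
#' by the denominator floor are NA.
#'
#' @param object an \code{im_fit}.
#' @param ... unused.
#' @return K x 3 matrix (columns S11, S12, S22).
#' @export
residuals.im_fit <- function(object, ...) {
  b <- params_boundaries_gen(object$params)
  Pm <- target_masses(object$target, object$mu)
  Pim <- .cpp_im_masses(b, object$params$N1, object$params$N2,
                        object$params$m)
  out <- (Pim - Pm) / sqrt(Pm)
  out[Pm <= object$config$dens_floor] <- NA_real_
  colnames(out) <- c("S11", "S12", "S22")
  out
}

#' Plot migration profile, M(t) and rCCR
#'
#' Draws the fitted migration rate m(t) (log-time axis) and, in a second
#' panel, the cumulative migration probability M(t) with the relative cross
#' coalescence rate of the target overlaid as a step function.
#'
#' @param x an \code{im_fit}.
#' @param years logical: time axis in years (default) or generations.
#' @param ... passed to \code{plot}.
#' @export
plot.im_fit <- function(x, years = TRUE, ...) {
  b <- params_boundaries_gen(x$params)
  tax <- if (years) generations_to_years(b, x$gen_time) else b
  tax[1L] <- tax[2L] / 4  # log axis cannot show 0
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tax, x$params$m, type = "s", log = "x",
                 xlab = if (years) "years ago" else "generations ago",
                 ylab = "m(t) per generation", ...)
  graphics::plot(tax, x$M, type = "s", log = "x", ylim = c(0, 1),
                 xlab = if (years) "years ago" else "generations ago",
                 ylab = "M(t)")
  graphics::lines(tax, rccr(x$target), type = "s", lty = 2, col = "grey40")
  graphics::legend("bottomright", c("M(t)", "rCCR"), lty = c(1, 2),
                   col = c("black", "grey40"), bty = "n")
  invisible(x)
}
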
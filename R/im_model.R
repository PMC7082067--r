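#' Isolation-migration model parameters
#'
#' A two-island model with piecewise-constant diploid sizes N1(t), N2(t) and
#' a piecewise-constant symmetric migration rate m(t) (per lineage per
#' generation), one value of each per parameter segment of a time grid.
#'
#' @param grid a \code{time_grid}.
#' @param N1,N2 diploid population sizes per segment, in (0, 1e7].
#' @param m symmetric migration rates per segment, nonnegative.
#' @return an object of class \code{im_params}.
#' @export
im_params <- function(grid, N1, N2, m) {
  stopifnot(inherits(grid, "time_grid"))
  K <- grid$n_segments
  if (length(N1) == 1L) N1 <- rep(N1, K)
  if (length(N2) == 1L) N2 <- rep(N2, K)
  if (length(m) == 1L) m <- rep(m, K)
  if (length(N1) != K || length(N2) != K || length(m) != K)
    stop("N1, N2, m must each have one value per segment (", K, ")")
  if (any(!is.finite(N1)) || any(!is.finite(N2)) || any(N1 <= 0) || any(N2 <= 0))
    stop("population sizes must be positive and finite")
  if (any(N1 > 1e7) || any(N2 > 1e7))
    stop("population sizes are capped at 10,000,000")
  if (any(!is.finite(m)) || any(m < 0))
    stop("migration rates must be nonnegative and finite")
  structure(list(grid = grid, N1 = as.numeric(N1), N2 = as.numeric(N2),
                 m = as.numeric(m)),
            class = "im_params")
}

#' @export
print.im_params <- function(x, ...) {
  cat("isolation-migration parameters over", x$grid$n_segments, "segments\n")
  cat("  N1 range:", signif(range(x$N1), 4), "\n")
  cat("  N2 range:", signif(range(x$N2), 4), "\n")
  cat("  m  range:", signif(range(x$m), 4), "per lineage per generation\n")
  invisible(x)
}

#' Rate generator of the pair process
#'
#' The instantaneous 4x4 generator over states (S11, S12, S22, C): both
#' lineages in island 1, one in each island, both in island 2, coalesced.
#' A lineage migrates at rate m; a pair sharing island i coalesces at rate
#' 1/(2 Ni). Rows sum to zero; C is absorbing.
#'
#' @param m symmetric migration rate per lineage per generation.
#' @param N1,N2 diploid sizes.
#' @return 4x4 matrix with dimnames (S11, S12, S22, C).
#' @export
build_generator <- function(m, N1, N2) {
  if (!all(is.finite(c(m, N1, N2)))) stop("non-finite generator parameters")
  if (m < 0 || N1 <= 0 || N2 <= 0) stop("parameters out of range")
  Q <- .cpp_im_generator(m, N1, N2)
  dimnames(Q) <- list(c("S11", "S12", "S22", "C"),
                      c("S11", "S12", "S22", "C"))
  Q
}

# boundaries of the parameter segments in generations (left boundaries)
params_boundaries_gen <- function(params) segment_boundaries_gen(params$grid)

#' Coalescence-time density under the IM model
#'
#' The density of the pairwise coalescence time given a start state,
#' f(t | s0) = sum over uncoalesced states of P(state at t | s0) times the
#' coalescence hazard of that state, computed by chaining per-segment matrix
#' exponentials of the pair-process generator.
#'
#' @param params an \code{im_params}.
#' @param s0 start state: one of \code{"S11"}, \code{"S12"}, \code{"S22"}.
#' @param eval_times times in generations (>= 0).
#' @return density values, per generation.
#' @export
im_density <- function(params, s0 = c("S11", "S12", "S22"), eval_times) {
  stopifnot(inherits(params, "im_params"))
  s0 <- match.arg(s0)
  if (any(eval_times < 0)) stop("eval_times must be >= 0")
  d <- .cpp_im_density(as.numeric(eval_times), params_boundaries_gen(params),
                       params$N1, params$N2, params$m, FALSE)
  d[match(s0, c("S11", "S12", "S22")), ]
}

#' Survival function of the pairwise coalescence time
#'
#' @inheritParams im_density
#' @return P(not yet coalesced by t | s0).
#' @export
im_survival <- function(params, s0 = c("S11", "S12", "S22"), eval_times) {
  stopifnot(inherits(params, "im_params"))
  s0 <- match.arg(s0)
  if (any(eval_times < 0)) stop("eval_times must be >= 0")
  d <- .cpp_im_density(as.numeric(eval_times), params_boundaries_gen(params),
                       params$N1, params$N2, params$m, TRUE)
  d[match(s0, c("S11", "S12", "S22")), ]
}

#' Cumulative migration probability M(t)
#'
#' M(t) = 1 - exp(-integral of m from 0 to t): the probability that a single
#' lineage has migrated at least once by time t, interpretable as the
#' proportion of cross-population ancestry that has already merged at t.
#' The piecewise-constant rate is integrated exactly segment by segment.
#'
#' @param params an \code{im_params}.
#' @param eval_times times in generations; defaults to the segment left
#'   boundaries.
#' @return M values in [0, 1).
#' @export
cumulative_migration <- function(params, eval_times = NULL) {
  stopifnot(inherits(params, "im_params"))
  b <- params_boundaries_gen(params)
  if (is.null(eval_times)) eval_times <- b
  if (any(eval_times < 0)) stop("eval_times must be >= 0")
  cum <- c(0, cumsum(params$m[-length(params$m)] * diff(b)))
  idx <- findInterval(eval_times, b)
  integral <- cum[idx] + params$m[idx] * (eval_times - b[idx])
  1 - exp(-integral)
}

#' Coalescence rates implied by an IM model
#'
#' Converts the model's coalescence-time distributions into piecewise-
#' constant hazard rates on a grid, for direct comparison with estimated
#' rate tables: the rate on segment [t_i, t_{i+1}) is the exact average
#' hazard log(S(t_i)/S(t_{i+1})) / (t_{i+1} - t_i) per start state. The
#' open-ended final segment is averaged over one extra span equal to the
#' last finite segment width. Segments where survival underflows are
#' reported at a documented cap (10 per generation).
#'
#' @param params an \code{im_params}.
#' @param boundaries_gen optional vector of left boundaries (generations,
#'   first must be 0) on which to report rates; defaults to the parameter
#'   segment boundaries. A finer grid gives a sharper piecewise
#'   representation of the model.
#' @return a three-rate \code{rate_table} in mutation-scaled units
#'   (columns lambda_00 = within island 1, lambda_01 = cross,
#'   lambda_11 = within island 2).
#' @export
im_implied_coalrates <- function(params, boundaries_gen = NULL) {
  stopifnot(inherits(params, "im_params"))
  mu <- params$grid$mu
  if (is.null(boundaries_gen)) boundaries_gen <- params_boundaries_gen(params)
  if (boundaries_gen[1L] != 0) stop("first boundary must be 0")
  K <- length(boundaries_gen)
  w_last <- boundaries_gen[K] - boundaries_gen[K - 1L]
  bx <- c(boundaries_gen, boundaries_gen[K] + w_last)
  S <- .cpp_im_density(bx, params_boundaries_gen(params),
                       params$N1, params$N2, params$m, TRUE)
  cap <- 10
  lam <- matrix(0, nrow = K, ncol = 3)
  for (s in 1:3) {
    Ss <- S[s, ]
    lam_s <- ifelse(Ss[-1L] <= 0 | Ss[-length(Ss)] <= 0,
                    cap,
                    log(Ss[-length(Ss)] / Ss[-1L]) / diff(bx))
    lam[, s] <- pmin(lam_s, cap)
  }
  # rates per generation -> per unit mutation-scaled time
  rate_table(left = boundaries_gen * mu,
             right = c(boundaries_gen[-1L], Inf) * mu,
             lambdas = lam / mu)
}
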
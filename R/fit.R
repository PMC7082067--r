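#' Fitting configuration
#'
#' @param beta1 regularization weight on migration (penalty
#'   \code{beta1 * m_i * dt_i} summed over segments, i.e. beta1 times the
#'   time-integral of m). Default 1e-8.
#' @param beta2 regularization weight on the relative size difference
#'   \code{((N1-N2)/(N1+N2))^2} per segment. Default 1e-6.
#' @param N_max population-size cap (default 1e7).
#' @param N_min lower bound on population sizes during optimization.
#' @param m_max upper bound on per-generation migration rates.
#' @param M_report_cap reporting cut-off: migration rates after M(t) first
#'   exceeds this value are masked in summaries (default 0.999).
#' @param dens_floor residual terms whose target density (per generation)
#'   falls below this floor are skipped (default 1e-12).
#' @param eps offset for the log-migration parameterization log(m + eps).
#' @param maxit,factr L-BFGS-B control parameters.
#' @param n_starts number of deterministic optimization passes (each pass
#'   restarts L-BFGS-B from the previous optimum).
#' @return a list of class \code{fit_config}.
#' @export
fit_config <- function(beta1 = 1e-8, beta2 = 1e-6, N_max = 1e7, N_min = 10,
                       m_max = 0.1, M_report_cap = 0.999, dens_floor = 1e-12,
                       eps = 1e-12, maxit = 1000L, factr = 1e2, n_starts = 2L,
                       residual = c("density", "mass")) {
  stopifnot(beta1 >= 0, beta2 >= 0, N_max > 0, dens_floor >= 0, eps > 0)
  residual <- match.arg(residual)
  structure(list(beta1 = beta1, beta2 = beta2, N_max = N_max, N_min = N_min,
                 m_max = m_max, M_report_cap = M_report_cap,
                 dens_floor = dens_floor, eps = eps, maxit = as.integer(maxit),
                 factr = factr, n_starts = as.integer(n_starts),
                 residual = residual),
            class = "fit_config")
}

# grid whose parameter segments are exactly the rows of a rate table
grid_from_rate_table <- function(target, mu) {
  b <- target$left_time_boundary
  n <- nrow(target)
  pat <- parse_time_pattern(sprintf("%d*1", n))
  structure(
    list(boundaries_scaled = b,
         segment_of_atomic = seq_len(n),
         segment_left_scaled = b,
         pattern = pat,
         n_segments = n,
         n_atomic = n,
         mu = mu,
         N_ref = NA_real_,
         n_haplotype_pairs = 1L),
    class = "time_grid")
}

# target per-segment coalescence masses S(t_i) - S(t_{i+1}) from the
# piecewise-exponential implied by the table (final segment: remaining
# mass), K x 3 over start states
target_masses <- function(target, mu) {
  b <- target$left_time_boundary / mu
  K <- length(b)
  vapply(c("S11", "S12", "S22"), function(s) {
    S <- msmc_tmrca_survival(target, s, b, mu)
    c(S[-K] - S[-1L], S[K])
  }, numeric(K))
}

# target densities (per generation) at segment right boundaries, each
# evaluated with that segment's own hazard (left-continuous); the final
# open-ended segment is evaluated one last-segment span past its left
# boundary. K x 3 over start states.
target_densities <- function(target, mu) {
  b <- target$left_time_boundary / mu
  K <- length(b)
  br <- c(b[-1L], b[K] + (b[K] - b[K - 1L]))
  vapply(c("S11", "S12", "S22"), function(s) {
    lam <- rate_column_gen(target, s, mu)
    lam * msmc_tmrca_survival(target, s, br, mu)
  }, numeric(K))
}

# residual targets per the configured convention
target_residual_matrix <- function(target, mu, config) {
  if (config$residual == "density") target_densities(target, mu)
  else target_masses(target, mu)
}

#' Regularized chi-square discrepancy
#'
#' The objective minimized by the fit: for every time segment and all
#' three start states, the squared difference between the coalescence
#' probability mass the model places in the segment and the mass implied
#' by the target rate table, scaled by the target mass, plus the migration
#' and size-difference regularization terms. Comparing per-segment masses
#' puts model and target through identical piecewise machinery, so the
#' residual term vanishes exactly when the model reproduces the table.
#'
#' @param params an \code{im_params} on the target's grid.
#' @param target a three-rate \code{rate_table}.
#' @param config a \code{fit_config}.
#' @return nonnegative scalar.
#' @export
chi_square <- function(params, target, config = fit_config()) {
  stopifnot(inherits(params, "im_params"), inherits(target, "rate_table"))
  if (!is_cross_table(target)) stop("target must have three lambda columns")
  mu <- params$grid$mu
  b <- params_boundaries_gen(params)
  if (length(b) != nrow(target) ||
      max(abs(b * mu - target$left_time_boundary)) > 1e-9 * max(b * mu))
    stop("params and target do not share a grid")
  Pm <- target_residual_matrix(target, mu, config)
  x <- c(log(params$N1), log(params$N2), log(params$m + config$eps))
  .cpp_im_chisq(x, b, Pm, segment_widths_gen(params$grid),
                config$beta1, config$beta2, config$dens_floor, config$eps,
                config$residual == "density")
}

#' Relative cross coalescence rate
#'
#' The classical heuristic separation profile 2*lambda_01 /
#' (lambda_00 + lambda_11) per segment, ranging from 0 (fully separated)
#' to about 1 (panmictic).
#'
#' @param target a three-rate \code{rate_table}.
#' @return numeric vector, one value per segment.
#' @export
rccr <- function(target) {
  stopifnot(inherits(target, "rate_table"))
  if (!is_cross_table(target)) stop("target must have three lambda columns")
  denom <- target$lambda_00 + target$lambda_11
  ifelse(denom > 0, 2 * target$lambda_01 / denom, 0)
}

# coordinate-descent sweeps over the segments: starting from the
# deterministic initialization, optimize each segment's (N1, N2, m) in turn
# against the full downstream objective (all residual masses from that
# segment onward, plus penalties), propagating the start-state occupancy
# rows across accepted segments. Exact coordinate descent on the joint
# chi-square, so the objective is nonincreasing; deterministic.
fit_sequential <- function(target, mu, config, Pm, init, n_sweeps = 4L,
                           first_direction = c("forward", "backward")) {
  first_direction <- match.arg(first_direction)
  K <- nrow(target)
  b <- target$left_time_boundary / mu
  w <- c(diff(b), b[K] - b[K - 1L])
  N1 <- init$N1; N2 <- init$N2; m <- init$m
  lower <- c(log(config$N_min), log(config$N_min), log(config$eps))
  upper <- c(log(config$N_max), log(config$N_max), log(config$m_max))
  use_dens <- config$residual == "density"
  total_cost <- function() {
    .cpp_im_tail_chisq(diag(1, 3, 4), b, N1, N2, m, Pm, w,
                       config$beta1, config$beta2, config$dens_floor,
                       use_dens)
  }
  # occupancy rows at each segment left boundary under the current params
  occ_prefix <- function() {
    occs <- vector("list", K)
    occs[[1L]] <- diag(1, 3, 4)
    for (i in seq_len(K - 1L))
      occs[[i + 1L]] <- .cpp_im_propagate(occs[[i]], b[i + 1L] - b[i],
                                          N1[i], N2[i], m[i])
    occs
  }
  prev_total <- Inf
  backward <- first_direction == "backward"
  for (sweep in seq_len(n_sweeps)) {
    occs <- occ_prefix()
    ord <- if (backward) rev(seq_len(K)) else seq_len(K)
    for (i in ord) {
      idx <- i:K
      occ <- occs[[i]]
      seg_obj <- function(p) {
        N1[i] <- exp(p[1L]); N2[i] <- exp(p[2L])
        m[i] <- max(exp(p[3L]) - config$eps, 0)
        .cpp_im_tail_chisq(occ, b[idx], N1[idx], N2[idx], m[idx],
                           Pm[idx, , drop = FALSE], w[idx],
                           config$beta1, config$beta2, config$dens_floor,
                           use_dens)
      }
      p0 <- pmin(pmax(c(log(N1[i]), log(N2[i]), log(m[i] + config$eps)),
                      lower), upper)
      op <- stats::optim(p0, seg_obj, method = "L-BFGS-B", lower = lower,
                         upper = upper,
                         control = list(maxit = 100, factr = 1e3,
                                        pgtol = 1e-14))
      if (op$value <= seg_obj(p0)) {
        N1[i] <- min(exp(op$par[1L]), config$N_max)
        N2[i] <- min(exp(op$par[2L]), config$N_max)
        m[i] <- max(exp(op$par[3L]) - config$eps, 0)
      } else {
        # restore the incumbent values clobbered by the last evaluation
        N1[i] <- min(exp(p0[1L]), config$N_max)
        N2[i] <- min(exp(p0[2L]), config$N_max)
        m[i] <- max(exp(p0[3L]) - config$eps, 0)
      }
      if (!backward && i < K)
        occs[[i + 1L]] <- .cpp_im_propagate(occs[[i]], b[i + 1L] - b[i],
                                            N1[i], N2[i], m[i])
    }
    backward <- !backward
    total <- total_cost()
    if (prev_total - total < 1e-10 * max(1, abs(prev_total))) break
    prev_total <- total
  }
  list(N1 = N1, N2 = N2, m = m)
}

# deterministic initialization by direct model inversion: sizes from the
# inverse within-rates (exact for the pair process, whose within states
# coalesce at 1/(2 Ni)), then a sequential one-dimensional root solve for
# each segment's migration rate against the cross-pair coalescence mass
# (monotone in m, so the root is unique when it exists; boundary-clipped
# otherwise). This is the re-parameterization view of the fit; the
# chi-square optimization then polishes it under the regularization.
fit_init <- function(target, mu, config) {
  K <- nrow(target)
  b <- target$left_time_boundary / mu
  w <- c(diff(b), b[K] - b[K - 1L])
  N1 <- pmin(pmax(1 / (2 * pmax(target$lambda_00, 1e-12) * mu), config$N_min),
             config$N_max)
  N2 <- pmin(pmax(1 / (2 * pmax(target$lambda_11, 1e-12) * mu), config$N_min),
             config$N_max)
  Pm <- target_masses(target, mu)
  m <- numeric(K)
  occ <- diag(1, 3, 4)
  m_lo <- 1e-10
  for (i in seq_len(K)) {
    Sin <- sum(occ[2L, 1:3])
    cross_mass <- function(mi) {
      out <- .cpp_im_propagate(occ, w[i], N1[i], N2[i], mi)
      Sin - sum(out[2L, 1:3])
    }
    tgt <- Pm[i, 2L]
    if (i == K) {
      lamt <- target$lambda_01[K] * mu
      tgt <- Sin * (1 - exp(-lamt * w[i]))
    }
    if (tgt <= config$dens_floor || cross_mass(m_lo) >= tgt) {
      m[i] <- m_lo
    } else if (cross_mass(config$m_max) <= tgt) {
      m[i] <- config$m_max * 0.9
    } else {
      r <- stats::uniroot(function(lm) cross_mass(exp(lm)) - tgt,
                          lower = log(m_lo), upper = log(config$m_max),
                          tol = 1e-10)
      m[i] <- exp(r$root)
    }
    occ <- .cpp_im_propagate(occ, w[i], N1[i], N2[i], m[i])
  }
  list(N1 = N1, N2 = N2, m = m)
}

#' Fit the isolation-migration model to a rate table
#'
#' Minimizes the regularized chi-square discrepancy between the two-island
#' model's coalescence-time densities and those implied by an estimated
#' three-rate table, re-parameterizing the rate triple
#' (lambda_00, lambda_01, lambda_11) into time-dependent sizes N1(t), N2(t)
#' and a symmetric migration rate m(t). Optimization is bounded L-BFGS-B in
#' log-parameter space from a deterministic initialization (sizes from
#' inverse within-rates, migration from the relative cross coalescence
#' rate profile); the fit is fully reproducible from its inputs.
#'
#' @param target a three-rate \code{rate_table} (e.g. from
#'   \code{\link{combine_cross_coal}} or \code{\link{exact_coal_rates}}).
#' @param mu mutation rate per bp per generation used to unscale the table.
#' @param config a \code{fit_config}.
#' @param gen_time generation time in years, used only for reporting.
#' @return an object of class \code{im_fit}; see
#'   \code{\link{summary.im_fit}}, \code{\link{coef.im_fit}},
#'   \code{\link{predict.im_fit}}, \code{\link{plot.im_fit}}.
#' @examples
#' grid <- make_time_grid("1*2+25*1+1*2+1*3")
#' truth <- im_params(grid, N1 = 20000, N2 = 20000,
#'                    m = ifelse(segment_boundaries_gen(grid) > 2500 &
#'                               segment_boundaries_gen(grid) < 3200, 1e-3, 0))
#' tab <- im_implied_coalrates(truth)
#' fit <- im_fit(tab)
#' summary(fit)
#' @export
im_fit <- function(target, mu = 1.25e-8, config = fit_config(),
                   gen_time = 29) {
  stopifnot(inherits(target, "rate_table"))
  if (!is_cross_table(target)) stop("target must have three lambda columns")
  grid <- grid_from_rate_table(target, mu)
  K <- grid$n_segments
  b <- segment_boundaries_gen(grid)
  dtv <- segment_widths_gen(grid)
  Pm <- target_residual_matrix(target, mu, config)
  n_skipped <- sum(Pm <= config$dens_floor)

  init <- fit_init(target, mu, config)
  x0 <- c(log(init$N1), log(init$N2), log(init$m + config$eps))
  lower <- c(rep(log(config$N_min), 2 * K), rep(log(config$eps), K))
  upper <- c(rep(log(config$N_max), 2 * K), rep(log(config$m_max), K))
  obj <- function(x) .cpp_im_chisq(x, b, Pm, dtv, config$beta1, config$beta2,
                                   config$dens_floor, config$eps,
                                   config$residual == "density")
  chi2_init <- obj(x0)
  # two deterministic candidates: the forward model inversion, refined by
  # forward-first coordinate sweeps, and a minimal-migration start refined
  # by backward-first sweeps (which builds migration from the deep end and
  # so favors the least-migration solution under the beta1 penalty); each
  # candidate is then polished jointly by bounded L-BFGS-B, and the best
  # final objective wins.
  low_init <- list(N1 = init$N1, N2 = init$N2,
                   m = rep(config$eps, length(init$m)))
  cands <- list(fit_sequential(target, mu, config, Pm, init,
                               first_direction = "forward"),
                fit_sequential(target, mu, config, Pm, low_init,
                               first_direction = "backward"))
  x <- NULL; chi2 <- Inf
  for (cand in cands) {
    xc <- pmin(pmax(c(log(cand$N1), log(cand$N2),
                      log(cand$m + config$eps)), lower), upper)
    chi2_c <- obj(xc)
    # joint polish in units of the candidate objective so L-BFGS-B's
    # relative stopping tests behave identically across scales
    scale <- max(chi2_c, .Machine$double.xmin)
    obj_sc <- function(x) obj(x) / scale
    res <- NULL
    xp <- xc
    for (pass in seq_len(config$n_starts)) {
      res <- stats::optim(xp, obj_sc, method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(maxit = config$maxit,
                                         factr = config$factr,
                                         pgtol = 1e-12))
      xp <- res$par
    }
    chi2_p <- res$value * scale
    if (chi2_p > chi2_c) {  # polish must never lose to its own start
      chi2_p <- chi2_c
      xp <- xc
    }
    if (chi2_p < chi2) {
      chi2 <- chi2_p
      x <- xp
    }
  }
  res <- list(convergence = 0L, counts = NA, message = NULL)
  status <- if (chi2 <= chi2_init + 1e-12) "converged" else "no-improvement"
  if (res$convergence != 0 && chi2 > chi2_init)
    status <- "not-converged"
  params <- im_params(grid,
                      N1 = pmin(exp(x[seq_len(K)]), config$N_max),
                      N2 = pmin(exp(x[K + seq_len(K)]), config$N_max),
                      m = pmax(0, exp(x[2 * K + seq_len(K)]) - config$eps))
  M <- cumulative_migration(params)
  structure(list(params = params, M = M, chi2 = chi2, chi2_init = chi2_init,
                 status = status, optim = res[c("convergence", "counts",
                                                "message")],
                 config = config, target = target, mu = mu,
                 gen_time = gen_time, n_terms_skipped = n_skipped),
            class = "im_fit")
}

#' Fitted-model report table
#'
#' One row per time segment: 0-based index, left boundary in generations
#' and years, fitted sizes, migration rate and cumulative migration
#' probability. Migration rates after M(t) first exceeds the reporting
#' cut-off are masked (NA), as estimates there are unconstrained.
#'
#' @param x an \code{im_fit}.
#' @param mask logical: mask migration rates beyond the M cut-off
#'   (default TRUE).
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.im_fit <- function(x, ..., mask = TRUE) {
  b <- params_boundaries_gen(x$params)
  m <- x$params$m
  if (mask) {
    over <- which(x$M >= x$config$M_report_cap)
    if (length(over) > 1L) m[over[-1L]] <- NA_real_
  }
  data.frame(time_index = seq_along(b) - 1L,
             left_boundary_gen = b,
             left_boundary_years = generations_to_years(b, x$gen_time),
             N1 = x$params$N1, N2 = x$params$N2, m = m, M = x$M)
}

#' Write the fitted-model report
#'
#' Tab-separated: time_index, left boundary in generations, N1, N2, m, M.
#'
#' @param fit an \code{im_fit}.
#' @param path output file.
#' @export
write_im_fit <- function(fit, path) {
  df <- as.data.frame(fit, mask = FALSE)
  lines <- c(paste(c("time_index", "left_boundary_gen", "N1", "N2", "m", "M"),
                   collapse = "\t"),
             sprintf("%d\t%.14g\t%.14g\t%.14g\t%.14g\t%.14g",
                     df$time_index, df$left_boundary_gen, df$N1, df$N2,
                     df$m, df$M))
  writeLines(lines, path)
  invisible(path)
}
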
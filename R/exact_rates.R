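# Exact pairwise coalescence rates for a demographic scenario.
#
# A pair of lineages is tracked on the finite CTMC whose states are the
# unordered deme assignments plus an absorbing coalesced state. Within an
# epoch the generator is constant (migration moves one lineage at a time;
# a pair sharing deme d coalesces at rate 1/(2 N_d)) and the occupancy is
# propagated by a dense matrix exponential; split and pulse events act as
# instantaneous stochastic relabeling matrices (products of the
# single-lineage move probabilities). Hazards are reported as exact
# segment averages log(S(t_i)/S(t_{i+1})) / dt, which is what an ideal
# piecewise-constant rate estimator would return.

# single-lineage relabeling matrix for an instantaneous event
event_lineage_map <- function(event, deme_names) {
  D <- length(deme_names)
  L <- diag(D)
  dimnames(L) <- list(deme_names, deme_names)
  if (event$type == "split") {
    L[event$from, ] <- 0
    L[event$from, event$to] <- 1
  } else if (event$type == "pulse") {
    L[event$from, event$from] <- 1 - event$alpha
    L[event$from, event$to] <- L[event$from, event$to] + event$alpha
  } else stop("not an instantaneous event")
  L
}

# pair-state relabeling matrix from a single-lineage map (rows sum to 1)
pair_event_matrix <- function(L, pair_index) {
  D <- nrow(L)
  S <- nrow(pair_index$states)
  M <- matrix(0, S + 1L, S + 1L)
  for (s in seq_len(S)) {
    i <- pair_index$states[s, 1L]; j <- pair_index$states[s, 2L]
    for (a in seq_len(D)) for (b in a:D) {
      p <- if (i == j) {
        if (a == b) L[i, a] * L[i, b] else 2 * L[i, a] * L[i, b]
      } else {
        if (a == b) L[i, a] * L[j, a]
        else L[i, a] * L[j, b] + L[i, b] * L[j, a]
      }
      M[s, pair_index$of[a, b]] <- M[s, pair_index$of[a, b]] + p
    }
  }
  M[S + 1L, S + 1L] <- 1
  M
}

# index of unordered deme pairs; state S+1 is the coalesced state
make_pair_index <- function(D) {
  states <- which(upper.tri(matrix(0, D, D), diag = TRUE), arr.ind = TRUE)
  states <- states[order(states[, 1L], states[, 2L]), , drop = FALSE]
  of <- matrix(NA_integer_, D, D)
  for (s in seq_len(nrow(states))) {
    of[states[s, 1L], states[s, 2L]] <- s
    of[states[s, 2L], states[s, 1L]] <- s
  }
  list(states = states, of = of)
}

# generator of the pair CTMC on one epoch
pair_generator <- function(sizes, mig, pair_index) {
  D <- length(sizes)
  S <- nrow(pair_index$states)
  Q <- matrix(0, S + 1L, S + 1L)
  for (s in seq_len(S)) {
    i <- pair_index$states[s, 1L]; j <- pair_index$states[s, 2L]
    for (k in seq_len(D)) {
      if (k != i && mig[i, k] > 0) {
        tgt <- pair_index$of[k, j]
        Q[s, tgt] <- Q[s, tgt] + (if (i == j) 2 else 1) * mig[i, k]
      }
      if (j != i && k != j && mig[j, k] > 0) {
        tgt <- pair_index$of[i, k]
        Q[s, tgt] <- Q[s, tgt] + mig[j, k]
      }
    }
    if (i == j) Q[s, S + 1L] <- Q[s, S + 1L] + 1 / (2 * sizes[i])
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

deme_size_at <- function(spec, deme, t) {
  ep <- spec$demes[[deme]]
  ep$N[findInterval(t, ep$start_gen)]
}

migration_matrix_at <- function(spec, deme_names, t) {
  D <- length(deme_names)
  mig <- matrix(0, D, D, dimnames = list(deme_names, deme_names))
  for (e in spec$events) {
    if (e$type == "migration" && t >= e$start_gen && t < e$end_gen) {
      a <- e$demes[1L]; b <- e$demes[2L]
      mig[a, b] <- mig[a, b] + e$rate
      mig[b, a] <- mig[b, a] + e$rate
    }
  }
  mig
}

#' Exact coalescence rates for a scenario
#'
#' Computes the noise-free piecewise rate table (within population 1,
#' across, within population 2) that an ideal rate estimator would return
#' for a scenario, by exact propagation of the lineage-location CTMC
#' through the scenario's epochs and events. With a single sampled deme all
#' three columns coincide.
#'
#' @param spec a \code{scenario_spec}.
#' @param grid a \code{time_grid}; rates are averaged over its parameter
#'   segments (the open final segment over one extra last-segment span).
#' @param sample_demes the two demes whose pairs are tracked; defaults to
#'   the sampled demes (a single sampled deme is used for both).
#' @return a three-rate \code{rate_table} on the grid, mutation-scaled.
#' @export
exact_coal_rates <- function(spec, grid, sample_demes = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(grid, "time_grid"))
  deme_names <- names(spec$demes)
  if (is.null(sample_demes)) {
    sample_demes <- names(spec$samples)
    if (length(sample_demes) == 1L) sample_demes <- rep(sample_demes, 2L)
  }
  stopifnot(length(sample_demes) == 2L, all(sample_demes %in% deme_names))
  D <- length(deme_names)
  pidx <- make_pair_index(D)
  S <- nrow(pidx$states)

  b_gen <- segment_boundaries_gen(grid)
  K <- length(b_gen)
  horizon <- b_gen[K] + (b_gen[K] - b_gen[K - 1L])
  inst <- Filter(function(e) e$type != "migration", spec$events)
  inst_t <- vapply(inst, `[[`, numeric(1L), "time_gen")
  if (any(inst_t > horizon))
    stop("event at ", max(inst_t),
         " generations lies beyond the grid horizon (", round(horizon), ")")
  mig_t <- unlist(lapply(Filter(function(e) e$type == "migration",
                                spec$events),
                         function(e) c(e$start_gen, e$end_gen)))
  size_t <- unlist(lapply(spec$demes, function(ep) ep$start_gen))
  eval_t <- c(b_gen, horizon)
  brk <- sort(unique(c(eval_t, inst_t, mig_t, size_t)))
  brk <- brk[brk <= horizon]

  # occupancy rows: one per start state
  i1 <- match(sample_demes[1L], deme_names)
  i2 <- match(sample_demes[2L], deme_names)
  P <- matrix(0, 3L, S + 1L)
  P[1L, pidx$of[i1, i1]] <- 1
  P[2L, pidx$of[i1, i2]] <- 1
  P[3L, pidx$of[i2, i2]] <- 1

  surv <- matrix(NA_real_, 3L, length(eval_t))
  record <- function(t, P) {
    hit <- which(abs(eval_t - t) < 1e-9)
    for (h in hit) surv[, h] <<- 1 - P[, S + 1L]
  }
  record(brk[1L], P)
  for (k in seq_len(length(brk) - 1L)) {
    t0 <- brk[k]; t1 <- brk[k + 1L]
    # events at t0 fire before the interval starting at t0
    for (ei in which(abs(inst_t - t0) < 1e-9)) {
      L <- event_lineage_map(inst[[ei]], deme_names)
      P <- P %*% pair_event_matrix(L, pidx)
    }
    sizes <- vapply(deme_names, function(d) deme_size_at(spec, d, t0),
                    numeric(1L))
    mig <- migration_matrix_at(spec, deme_names, t0)
    Q <- pair_generator(sizes, mig, pidx)
    P <- P %*% .cpp_expm(Q * (t1 - t0))
    record(t1, P)
  }

  lam <- matrix(0, K, 3L)
  for (s in 1:3) {
    Ss <- surv[s, ]
    dts <- diff(eval_t)
    lam_s <- ifelse(Ss[-1L] <= 0 | Ss[-length(Ss)] <= 0, 10,
                    log(pmax(Ss[-length(Ss)], 1e-300) /
                        pmax(Ss[-1L], 1e-300)) / dts)
    lam[, s] <- pmin(pmax(lam_s, 0), 10)
  }
  rate_table(left = b_gen * grid$mu,
             right = c(b_gen[-1L], Inf) * grid$mu,
             lambdas = lam / grid$mu)
}
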
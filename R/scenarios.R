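#' Demographic scenario specification
#'
#' A scenario describes, backward in time: a set of demes with
#' piecewise-constant diploid sizes; split events (all lineages of one deme
#' move to another); pulse admixture events (each lineage of one deme moves
#' to another with probability alpha); windows of continuous symmetric
#' migration between two demes; the sampling configuration; and sequence
#' simulation parameters.
#'
#' @param demes named list: for each deme a data.frame with columns
#'   \code{start_gen} (epoch start, backward; first must be 0) and \code{N}
#'   (diploid size on that epoch).
#' @param events list of event lists, each with a \code{type} of
#'   \code{"split"} (fields time_gen, from, to), \code{"pulse"} (time_gen,
#'   from, to, alpha) or \code{"migration"} (start_gen, end_gen, demes =
#'   character(2), rate = symmetric per-lineage per-generation rate).
#' @param samples named integer vector: haplotypes sampled per deme.
#' @param mu,rho mutation and recombination rates per bp per generation.
#' @param chrom_length_bp,n_chrom sequence length per chromosome and
#'   number of chromosomes for sequence simulation.
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(demes, events = list(), samples,
                          mu = 1.25e-8, rho = 1e-8,
                          chrom_length_bp = 1e8, n_chrom = 22L) {
  stopifnot(is.list(demes), length(names(demes)) == length(demes))
  for (d in names(demes)) {
    ep <- demes[[d]]
    stopifnot(is.data.frame(ep), all(c("start_gen", "N") %in% names(ep)))
    if (ep$start_gen[1L] != 0 || any(diff(ep$start_gen) <= 0))
      stop("epochs of deme ", d, " must start at 0 and be time-ordered")
    if (any(ep$N <= 0)) stop("sizes must be positive")
  }
  ev_times <- vapply(events, function(e)
    if (e$type == "migration") e$start_gen else e$time_gen, numeric(1L))
  if (is.unsorted(ev_times)) events <- events[order(ev_times)]
  for (e in events) {
    if (!e$type %in% c("split", "pulse", "migration"))
      stop("unknown event type ", e$type)
    if (e$type == "pulse" && (e$alpha < 0 || e$alpha > 1))
      stop("pulse fraction must be in [0, 1]")
  }
  stopifnot(all(names(samples) %in% names(demes)))
  structure(list(demes = demes, events = events,
                 samples = samples, mu = mu, rho = rho,
                 chrom_length_bp = chrom_length_bp,
                 n_chrom = as.integer(n_chrom)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario:", length(x$demes), "demes,", length(x$events), "events,",
      sum(x$samples), "haplotypes sampled\n")
  for (e in x$events) {
    if (e$type == "migration")
      cat(sprintf("  migration %s<->%s rate %.3g over %.0f-%.0f gen\n",
                  e$demes[1L], e$demes[2L], e$rate, e$start_gen, e$end_gen))
    else if (e$type == "pulse")
      cat(sprintf("  pulse %s->%s alpha %.3g at %.0f gen\n",
                  e$from, e$to, e$alpha, e$time_gen))
    else
      cat(sprintf("  split %s->%s at %.0f gen\n", e$from, e$to, e$time_gen))
  }
  invisible(x)
}

# --- plain-text serialization ------------------------------------------------

#' Write / read a scenario file
#'
#' Plain key-value text format, one declaration per line (\code{deme},
#' \code{size}, \code{event}, \code{sample}, \code{mu}, \code{rho},
#' \code{length}, \code{chromosomes}); round-trips losslessly.
#'
#' @param spec a \code{scenario_spec}.
#' @param path file path.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  ln <- character(0)
  for (d in names(spec$demes)) {
    ln <- c(ln, paste("deme", d))
    ep <- spec$demes[[d]]
    ln <- c(ln, sprintf("size %s %.10g %.10g", d, ep$start_gen, ep$N))
  }
  for (e in spec$events) {
    ln <- c(ln, switch(e$type,
      split = sprintf("event split %.10g %s %s", e$time_gen, e$from, e$to),
      pulse = sprintf("event pulse %.10g %s %s %.10g",
                      e$time_gen, e$from, e$to, e$alpha),
      migration = sprintf("event migration %.10g %.10g %s %s %.10g",
                          e$start_gen, e$end_gen, e$demes[1L], e$demes[2L],
                          e$rate)))
  }
  ln <- c(ln, sprintf("sample %s %d", names(spec$samples), spec$samples),
          sprintf("mu %.10g", spec$mu),
          sprintf("rho %.10g", spec$rho),
          sprintf("length %.10g", spec$chrom_length_bp),
          sprintf("chromosomes %d", spec$n_chrom))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  demes <- list(); events <- list(); samples <- integer(0)
  mu <- 1.25e-8; rho <- 1e-8; len <- 1e8; nch <- 22L
  for (l in ln) {
    f <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
    switch(f[1L],
      deme = { demes[[f[2L]]] <- data.frame(start_gen = numeric(0),
                                            N = numeric(0)) },
      size = { demes[[f[2L]]] <- rbind(demes[[f[2L]]],
                 data.frame(start_gen = as.numeric(f[3L]),
                            N = as.numeric(f[4L]))) },
      event = {
        events[[length(events) + 1L]] <- switch(f[2L],
          split = list(type = "split", time_gen = as.numeric(f[3L]),
                       from = f[4L], to = f[5L]),
          pulse = list(type = "pulse", time_gen = as.numeric(f[3L]),
                       from = f[4L], to = f[5L], alpha = as.numeric(f[6L])),
          migration = list(type = "migration",
                           start_gen = as.numeric(f[3L]),
                           end_gen = as.numeric(f[4L]),
                           demes = c(f[5L], f[6L]),
                           rate = as.numeric(f[7L])),
          stop("unknown event kind ", f[2L]))
      },
      sample = { samples[f[2L]] <- as.integer(f[3L]) },
      mu = { mu <- as.numeric(f[2L]) },
      rho = { rho <- as.numeric(f[2L]) },
      length = { len <- as.numeric(f[2L]) },
      chromosomes = { nch <- as.integer(f[2L]) },
      stop("unknown scenario declaration: ", f[1L]))
  }
  scenario_spec(demes, events, samples, mu, rho, len, nch)
}

# --- predefined study scenarios ---------------------------------------------

#' Predefined demographic scenarios
#'
#' The simulation-study scenarios: two constant-size (20,000) populations
#' with (a) a clean split at time T; (b) a split plus a window of symmetric
#' post-split migration with a per-direction time-integral of 0.5 between
#' 10 and 15 kya; (c) a split at 75 kya plus an admixture pulse at 30 kya
#' from an unsampled deme diverging 1 Mya ago; (d) scenario (c) with a
#' factor-30 bottleneck in population 1 between 40 and 60 kya; and (e) a
#' single-population zigzag alternating between 3,000 and 30,000 over
#' exponentially growing intervals. Times given in kya are converted to
#' generations with \code{gen_time}.
#'
#' @param T_kya split time in kya (default 75).
#' @param alpha archaic admixture fraction for the pulse scenarios.
#' @param gen_time generation time in years (default 29).
#' @param haplotypes_per_deme haplotypes sampled per extant deme.
#' @param chrom_length_bp,n_chrom sequence simulation dimensions.
#' @return \code{scenario_clean_split} etc. return a single
#'   \code{scenario_spec}; \code{predefined_scenarios} returns a named list
#'   of the five defaults.
#' @export
scenario_clean_split <- function(T_kya = 75, gen_time = 29,
                                 haplotypes_per_deme = 4L,
                                 chrom_length_bp = 1e8, n_chrom = 22L) {
  Tg <- years_to_generations(T_kya * 1e3, gen_time)
  scenario_spec(
    demes = list(pop1 = data.frame(start_gen = 0, N = 20000),
                 pop2 = data.frame(start_gen = 0, N = 20000)),
    events = list(list(type = "split", time_gen = Tg,
                       from = "pop2", to = "pop1")),
    samples = c(pop1 = haplotypes_per_deme, pop2 = haplotypes_per_deme),
    chrom_length_bp = chrom_length_bp, n_chrom = n_chrom)
}

#' @rdname scenario_clean_split
#' @param mig_window_kya migration window (kya, recent and old edge).
#' @param total_migration per-direction time-integral of the migration rate
#'   over the window (default 0.5).
#' @export
scenario_split_with_migration <- function(T_kya = 75,
                                          mig_window_kya = c(10, 15),
                                          total_migration = 0.5,
                                          gen_time = 29,
                                          haplotypes_per_deme = 4L,
                                          chrom_length_bp = 1e8,
                                          n_chrom = 22L) {
  sp <- scenario_clean_split(T_kya, gen_time, haplotypes_per_deme,
                             chrom_length_bp, n_chrom)
  w <- years_to_generations(mig_window_kya * 1e3, gen_time)
  sp$events <- c(list(list(type = "migration", start_gen = w[1L],
                           end_gen = w[2L], demes = c("pop1", "pop2"),
                           rate = total_migration / (w[2L] - w[1L]))),
                 sp$events)
  sp
}

#' @rdname scenario_clean_split
#' @param pulse_kya admixture pulse time (kya).
#' @param Ta_kya archaic divergence time (kya).
#' @export
scenario_archaic <- function(alpha = 0.05, T_kya = 75, pulse_kya = 30,
                             Ta_kya = 1000, gen_time = 29,
                             haplotypes_per_deme = 4L,
                             chrom_length_bp = 1e8, n_chrom = 22L) {
  Tg <- years_to_generations(T_kya * 1e3, gen_time)
  Pg <- years_to_generations(pulse_kya * 1e3, gen_time)
  Ag <- years_to_generations(Ta_kya * 1e3, gen_time)
  ev <- list(list(type = "split", time_gen = Tg, from = "pop2", to = "pop1"),
             list(type = "split", time_gen = Ag, from = "archaic",
                  to = "pop1"))
  if (alpha > 0)
    ev <- c(list(list(type = "pulse", time_gen = Pg, from = "pop1",
                      to = "archaic", alpha = alpha)), ev)
  scenario_spec(
    demes = list(pop1 = data.frame(start_gen = 0, N = 20000),
                 pop2 = data.frame(start_gen = 0, N = 20000),
                 archaic = data.frame(start_gen = 0, N = 20000)),
    events = ev,
    samples = c(pop1 = haplotypes_per_deme, pop2 = haplotypes_per_deme),
    chrom_length_bp = chrom_length_bp, n_chrom = n_chrom)
}

#' @rdname scenario_clean_split
#' @param bottleneck_kya bottleneck window in population 1 (kya).
#' @param bottleneck_factor size reduction factor (default 30).
#' @export
scenario_archaic_bottleneck <- function(alpha = 0.05, T_kya = 75,
                                        pulse_kya = 30, Ta_kya = 1000,
                                        bottleneck_kya = c(40, 60),
                                        bottleneck_factor = 30,
                                        gen_time = 29,
                                        haplotypes_per_deme = 4L,
                                        chrom_length_bp = 1e8,
                                        n_chrom = 22L) {
  sp <- scenario_archaic(alpha, T_kya, pulse_kya, Ta_kya, gen_time,
                         haplotypes_per_deme, chrom_length_bp, n_chrom)
  bg <- years_to_generations(bottleneck_kya * 1e3, gen_time)
  sp$demes$pop1 <- data.frame(
    start_gen = c(0, bg[1L], bg[2L]),
    N = c(20000, 20000 / bottleneck_factor, 20000))
  sp
}

#' @rdname scenario_clean_split
#' @param n_haplotypes haplotypes sampled in the zigzag scenario.
#' @export
scenario_zigzag <- function(n_haplotypes = 8L, chrom_length_bp = 1e8,
                            n_chrom = 22L) {
  # sizes alternate between 3,000 and 30,000 at exponentially growing
  # knots (1k, 2k, ..., 256k generations), constant outside
  knots <- 1000 * 2^(0:8)
  N <- rep(c(30000, 3000), length.out = length(knots) + 1L)
  scenario_spec(
    demes = list(pop1 = data.frame(start_gen = c(0, knots), N = N)),
    events = list(),
    samples = c(pop1 = n_haplotypes),
    rho = 0.3e-8,
    chrom_length_bp = chrom_length_bp, n_chrom = n_chrom)
}

#' @rdname scenario_clean_split
#' @export
predefined_scenarios <- function(T_kya = 75, alpha = 0.05, gen_time = 29) {
  list(clean_split = scenario_clean_split(T_kya, gen_time),
       split_with_migration = scenario_split_with_migration(T_kya,
                                                            gen_time = gen_time),
       archaic = scenario_archaic(alpha, T_kya, gen_time = gen_time),
       archaic_bottleneck = scenario_archaic_bottleneck(alpha, T_kya,
                                                        gen_time = gen_time),
       zigzag = scenario_zigzag())
}
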
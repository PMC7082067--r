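#' Expand a haplotype-pair selection string
#'
#' Two forms are accepted, mirroring the conventional \code{-I} flag of the
#' pairwise rate estimators: a comma list of haplotype indices
#' (\code{"0,1,2,3"}), expanded to all k(k-1)/2 unordered pairs, or a comma
#' list of dash-separated pairs (\code{"0-4,0-5,..."}), taken verbatim.
#' Indices are 0-based.
#'
#' @param spec_text selection string.
#' @return integer matrix with two columns (0-based haplotype indices).
#' @examples
#' nrow(expand_pair_spec("0,1,2,3"))  # 6
#' @export
expand_pair_spec <- function(spec_text) {
  toks <- strsplit(spec_text, ",", fixed = TRUE)[[1L]]
  if (!length(toks)) stop("empty pair specification")
  dashed <- grepl("-", toks, fixed = TRUE)
  if (all(dashed)) {
    prs <- t(vapply(strsplit(toks, "-", fixed = TRUE), function(p) {
      if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p))))
        stop("bad pair token '", paste(p, collapse = "-"), "'")
      as.integer(p)
    }, integer(2L)))
  } else if (!any(dashed)) {
    idx <- suppressWarnings(as.integer(toks))
    if (anyNA(idx)) stop("bad haplotype index in '", spec_text, "'")
    if (anyDuplicated(idx)) stop("duplicate haplotype indices")
    if (length(idx) < 2L) stop("need at least two haplotypes")
    prs <- t(utils::combn(sort(idx), 2L))
  } else stop("mixed within- and cross-forms in pair specification")
  if (any(prs < 0)) stop("negative haplotype index")
  if (any(prs[, 1L] == prs[, 2L])) stop("self-pairs are not allowed")
  colnames(prs) <- c("hap1", "hap2")
  prs
}

#' Configuration of the pairwise rate estimator
#'
#' @param grid a \code{time_grid}; hidden states are its atomic intervals,
#'   with rates tied within parameter segments.
#' @param rho initial (or fixed) recombination rate per bp per generation.
#' @param est_rho estimate a single scalar effective recombination rate in
#'   the EM (default TRUE); FALSE freezes \code{rho}.
#' @param bin_bp window size in bp over which observations are aggregated
#'   (default 100).
#' @param max_iter EM iteration cap.
#' @param tol EM convergence tolerance on the composite log-likelihood.
#' @param lambda_bounds per-generation bounds on the coalescence rates.
#' @return a list of class \code{hmm_config}.
#' @export
hmm_config <- function(grid, rho = 1e-8, est_rho = TRUE, bin_bp = 100L,
                       max_iter = 20L, tol = 1e-2,
                       lambda_bounds = c(1e-9, 0.1)) {
  stopifnot(inherits(grid, "time_grid"), rho > 0, max_iter >= 1)
  structure(list(grid = grid, rho = rho, est_rho = est_rho,
                 bin_bp = as.integer(bin_bp), max_iter = as.integer(max_iter),
                 tol = tol, lambda_bounds = lambda_bounds),
            class = "hmm_config")
}

# het code per record for one haplotype pair: 0 hom, 1 het, 2 ambiguous
pair_het_codes <- function(alleles, h1, h2) {
  plain <- !grepl(",", alleles, fixed = TRUE)
  code <- integer(length(alleles))
  a1 <- substr(alleles[plain], h1, h1)
  a2 <- substr(alleles[plain], h2, h2)
  code[plain] <- as.integer(a1 != a2)
  if (any(!plain)) {
    code[!plain] <- vapply(strsplit(alleles[!plain], ",", fixed = TRUE),
                           function(opts) {
      het <- vapply(opts, function(s)
        substr(s, h1, h1) != substr(s, h2, h2), logical(1L))
      if (all(het)) 1L else if (!any(het)) 0L else 2L
    }, integer(1L))
  }
  code
}

# binned observations for one chromosome and pair
bin_pair_observations <- function(rec, h1, h2, bin_bp) {
  code <- pair_het_codes(rec$alleles, h1, h2)
  n_bins <- max(1L, as.integer(ceiling(max(rec$pos) / bin_bp)))
  .cpp_bin_observations(rec$pos, rec$called, code, bin_bp, n_bins)
}

# conditional mean times within intervals under a constant rate lambda0
interval_representatives <- function(tau, lambda0) {
  K <- length(tau)
  w <- diff(tau)
  rep_in <- tau[-K] + 1 / lambda0 - w * exp(-lambda0 * w) /
    (1 - exp(-lambda0 * w))
  c(rep_in, tau[K] + 1 / lambda0)
}

#' Estimate piecewise coalescence rates from sequence data
#'
#' Fits the pairwise SMC' hidden Markov model to multihetsep input: the
#' hidden state is the time interval containing the local pairwise tMRCA,
#' transitions follow the SMC' recombination process with piecewise-constant
#' coalescence rates, and emissions give the heterozygote probability per
#' window given the interval's representative time. Rates (tied within
#' parameter segments) and, optionally, a single scalar effective
#' recombination rate are optimized by expectation-maximization over the
#' composite likelihood of all selected haplotype pairs; the composite
#' log-likelihood is nondecreasing over iterations.
#'
#' @param files multihetsep file paths (or a list of multihetsep data
#'   frames), one per chromosome.
#' @param pairs an integer matrix from \code{\link{expand_pair_spec}}, or a
#'   selection string.
#' @param config an \code{hmm_config}.
#' @return a list of class \code{rate_estimate}: \code{table} (single-rate
#'   \code{rate_table}), \code{loglik} (per-iteration trace), \code{rho}
#'   (per bp per generation), \code{lambda_gen}, and \code{flags}.
#' @export
estimate_rates <- function(files, pairs, config) {
  stopifnot(inherits(config, "hmm_config"))
  if (is.character(pairs)) pairs <- expand_pair_spec(pairs)
  recs <- lapply(files, function(f)
    if (is.character(f)) read_multihetsep(f) else f)
  if (!length(recs) || all(vapply(recs, nrow, integer(1L)) == 0L))
    stop("empty input")
  nh <- unique(vapply(recs, n_haplotypes, integer(1L)))
  if (length(nh) != 1L) stop("inconsistent haplotype counts across files")
  if (any(pairs >= nh)) stop("haplotype index beyond input haplotype count")

  grid <- config$grid
  mu <- grid$mu
  tau <- grid$boundaries_scaled / mu
  seg <- grid$segment_of_atomic
  K <- grid$n_atomic
  nseg <- grid$n_segments
  bin <- config$bin_bp

  obs <- list()
  tot_het <- 0; tot_called <- 0
  for (ri in seq_along(recs)) {
    for (pi in seq_len(nrow(pairs))) {
      o <- bin_pair_observations(recs[[ri]], pairs[pi, 1L] + 1L,
                                 pairs[pi, 2L] + 1L, bin)
      obs[[length(obs) + 1L]] <- o
      tot_het <- tot_het + sum(o$het) + 0.5 * sum(o$amb)
      tot_called <- tot_called + sum(o$hom) + sum(o$het) + sum(o$amb)
    }
  }
  flags <- character(0)
  if (tot_het == 0) {
    flags <- c(flags, "no-informative-sites")
    warning("no heterozygous sites: rates are unidentified")
    pi_bp <- 2 * mu  # fall back on tMRCA of one generation scale
  } else pi_bp <- tot_het / tot_called
  lambda0 <- 2 * mu / pi_bp
  trep <- interval_representatives(tau, lambda0)
  p_het <- -expm1(-2 * trep * mu)

  lam_seg <- rep(lambda0, nseg)
  rho <- config$rho
  lb <- log(config$lambda_bounds[1L]); ub <- log(config$lambda_bounds[2L])
  loglik_trace <- numeric(0)
  for (iter in seq_len(config$max_iter)) {
    A <- .cpp_smc_transition(tau, lam_seg[seg], trep, 2 * rho * bin)
    pi0 <- .cpp_tmrca_marginal(tau, lam_seg[seg])
    C <- matrix(0, K, K); g0 <- numeric(K); ll <- 0
    for (o in obs) {
      es <- .cpp_hmm_estep(o$hom, o$het, o$amb, pi0, A, p_het)
      C <- C + es$counts; g0 <- g0 + es$gamma0; ll <- ll + es$loglik
    }
    loglik_trace <- c(loglik_trace, ll)
    if (iter > 1L && abs(ll - loglik_trace[iter - 1L]) < config$tol) break
    # M-step: maximize the expected complete-data objective
    par0 <- log(lam_seg)
    if (config$est_rho) par0 <- c(par0, log(rho))
    negq <- function(p) {
      lam <- exp(p[seq_len(nseg)])
      r <- if (config$est_rho) exp(p[nseg + 1L]) else rho
      -.cpp_hmm_q(tau, lam[seg], trep, 2 * r * bin, C, g0)
    }
    lower <- c(rep(lb, nseg), if (config$est_rho) log(1e-11))
    upper <- c(rep(ub, nseg), if (config$est_rho) log(1e-6))
    op <- stats::optim(par0, negq, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = list(maxit = 150))
    if (op$value <= negq(par0)) {
      lam_seg <- exp(op$par[seq_len(nseg)])
      if (config$est_rho) rho <- exp(op$par[nseg + 1L])
    }
  }
  seg_left <- grid$segment_left_scaled / mu
  tab <- rate_table(left = seg_left * mu,
                    right = c(seg_left[-1L], Inf) * mu,
                    lambdas = lam_seg / mu)
  structure(list(table = tab, loglik = loglik_trace, rho = rho,
                 lambda_gen = lam_seg, flags = flags, pairs = pairs,
                 config = config),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("pairwise SMC' rate estimate:", nrow(x$pairs), "pairs,",
      length(x$loglik), "EM iterations\n")
  cat("  final composite log-likelihood:", format(x$loglik[length(x$loglik)]),
      "\n")
  cat("  effective recombination rate:", signif(x$rho, 4), "per bp per gen\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Block bootstrap over multihetsep input
#'
#' Cuts the input into contiguous blocks of fixed physical length and, for
#' each replicate, samples blocks with replacement and concatenates them
#' into a pseudo-chromosome. Block boundaries never split a record.
#' Deterministic given the seed.
#'
#' @param files multihetsep paths or data frames.
#' @param block_length_bp block length in bp.
#' @param n_blocks blocks per replicate (default: as many as the input has).
#' @param n_reps number of replicates (default 20).
#' @param seed integer seed.
#' @return a list of length \code{n_reps}; each element a \code{multihetsep}
#'   data frame (pseudo-chromosome \code{"bs"}).
#' @export
block_bootstrap <- function(files, block_length_bp, n_blocks = NULL,
                            n_reps = 20L, seed = 1L) {
  stopifnot(block_length_bp > 0)
  recs <- lapply(files, function(f)
    if (is.character(f)) read_multihetsep(f) else f)
  blocks <- list()
  for (rec in recs) {
    for (ch in unique(rec$chrom)) {
      sub <- rec[rec$chrom == ch, , drop = FALSE]
      bi <- (sub$pos - 1L) %/% block_length_bp
      for (b in unique(bi)) {
        blk <- sub[bi == b, , drop = FALSE]
        blk$pos <- blk$pos - b * block_length_bp
        blk$called[1L] <- min(blk$called[1L], blk$pos[1L])
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
  }
  if (!length(blocks)) stop("no data to resample")
  if (is.null(n_blocks)) n_blocks <- length(blocks)
  if (block_length_bp * n_blocks >
      sum(vapply(recs, function(r) max(r$pos), numeric(1L))) * 2)
    stop("requested more sequence than the input provides")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pick <- sample.int(length(blocks), n_blocks, replace = TRUE)
    parts <- vector("list", n_blocks)
    for (k in seq_len(n_blocks)) {
      blk <- blocks[[pick[k]]]
      blk$chrom <- "bs"
      blk$pos <- blk$pos + (k - 1L) * block_length_bp
      parts[[k]] <- blk
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    class(out) <- c("multihetsep", "data.frame")
    reps[[r]] <- out
  }
  reps
}
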
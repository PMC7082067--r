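python_binary <- function() {
  p <- getOption("imtracer.python", Sys.which("python"))
  if (!nzchar(p)) stop("no python interpreter found (set options(imtracer.python=))")
  p
}

#' Simulate multihetsep files for a scenario
#'
#' Runs a coalescent-with-recombination simulation of the scenario (via the
#' bundled msprime helper script) and writes one multihetsep file per
#' chromosome. Output is fully determined by (spec, seed).
#'
#' @param spec a \code{scenario_spec}.
#' @param seed positive integer random seed.
#' @param out_dir output directory (created if needed).
#' @return character vector of written multihetsep paths.
#' @export
simulate_sequences <- function(spec, seed, out_dir = tempfile("sim")) {
  stopifnot(inherits(spec, "scenario_spec"), seed == as.integer(seed),
            seed > 0)
  scen <- tempfile(fileext = ".scenario")
  on.exit(unlink(scen))
  write_scenario(spec, scen)
  script <- system.file("python", "sim_scenario.py", package = "imtracer")
  if (!nzchar(script))
    script <- file.path("inst", "python", "sim_scenario.py")
  out <- suppressWarnings(
    system2(python_binary(), c(shQuote(script), shQuote(scen),
                               shQuote(out_dir), as.integer(seed)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("sequence simulation failed:\n", paste(out, collapse = "\n"))
  paths <- file.path(out_dir,
                     sprintf("chr%d.multihetsep.txt", seq_len(spec$n_chrom)))
  if (!all(file.exists(paths)))
    stop("simulation did not produce the expected files:\n",
         paste(out, collapse = "\n"))
  paths
}

# swap the two haplotypes of one individual in allele strings from a given
# parity vector (TRUE = swapped at that record)
swap_alleles <- function(alleles, hap_a, hap_b, swapped) {
  if (!any(swapped)) return(alleles)
  vapply(which(swapped), function(i) {
    paste(vapply(strsplit(alleles[i], ",", fixed = TRUE)[[1L]], function(s) {
      v <- strsplit(s, "")[[1L]]
      tmp <- v[hap_a]; v[hap_a] <- v[hap_b]; v[hap_b] <- tmp
      paste(v, collapse = "")
    }, character(1L)), collapse = ",")
  }, character(1L)) -> alleles_sub
  alleles[which(swapped)] <- alleles_sub
  alleles
}

#' Inject phasing switch errors
#'
#' Emulates statistical-phasing switch errors: for each individual
#' (consecutive haplotype pairs 1-2, 3-4, ...) and chromosome, switch
#' points are drawn as a Poisson process of the given per-bp rate; from
#' each switch point onward the individual's two haplotype labels are
#' exchanged (two consecutive switches restore the original phase).
#'
#' @param files multihetsep file paths.
#' @param rate_per_bp switch error rate per base pair (>= 0).
#' @param seed integer seed; output is deterministic given it.
#' @param out_dir directory for the corrupted copies.
#' @return paths of the corrupted files.
#' @export
inject_switch_errors <- function(files, rate_per_bp, seed,
                                 out_dir = tempfile("switch")) {
  stopifnot(rate_per_bp >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- character(length(files))
  for (fi in seq_along(files)) {
    rec <- read_multihetsep(files[[fi]])
    nh <- n_haplotypes(rec)
    n_ind <- nh %/% 2L
    if (rate_per_bp > 0 && nrow(rec) > 0L) {
      L <- max(rec$pos)
      for (ind in seq_len(n_ind)) {
        k <- stats::rpois(1L, rate_per_bp * L)
        if (k == 0L) next
        pts <- sort(stats::runif(k, 1, L))
        swapped <- (findInterval(rec$pos, pts) %% 2L) == 1L
        rec$alleles <- swap_alleles(rec$alleles, 2L * ind - 1L, 2L * ind,
                                    swapped)
      }
    }
    out[fi] <- file.path(out_dir, basename(files[[fi]]))
    write_multihetsep(rec, out[fi])
  }
  out
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
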
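test_that("panmictic scenario yields the constant coalescent rate", {
  g <- make_time_grid("8*1")
  sp <- scenario_clean_split(75, haplotypes_per_deme = 2L)
  sp$demes <- sp$demes["pop1"]
  sp$events <- list()
  sp$samples <- c(pop1 = 2L)
  tab <- exact_coal_rates(sp, g)
  mu <- g$mu
  for (cn in c("lambda_00", "lambda_01", "lambda_11"))
    expect_equal(tab[[cn]] * mu, rep(1 / 40000, 8), tolerance = 1e-9)
  expect_equal(rccr(tab), rep(1, 8), tolerance = 1e-9)
})

test_that("clean split forces a sharp 0-to-1 step in the rCCR", {
  g <- make_time_grid("1*2+25*1+1*2+1*3")
  Tg <- years_to_generations(75e3)
  tab <- exact_coal_rates(scenario_clean_split(75), g)
  b <- segment_boundaries_gen(g)
  r <- rccr(tab)
  pre <- which(b + c(diff(b), Inf) < Tg)   # segments fully before the split
  post <- which(b > Tg)
  expect_equal(r[pre], rep(0, length(pre)))
  expect_true(all(r[post] > 0.999))
  expect_equal(tab$lambda_01[pre], rep(0, length(pre)))
})

test_that("a zero admixture pulse is a no-op", {
  g <- make_time_grid("1*2+25*1+1*2+1*3")
  t0 <- exact_coal_rates(scenario_archaic(alpha = 0), g)
  t1 <- exact_coal_rates(scenario_clean_split(75), g)
  for (cn in c("lambda_00", "lambda_01", "lambda_11"))
    expect_equal(t0[[cn]], t1[[cn]], tolerance = 1e-9)
})

test_that("scenario files round-trip losslessly", {
  for (sp in list(scenario_clean_split(75),
                  scenario_split_with_migration(75),
                  scenario_archaic(0.05),
                  scenario_archaic_bottleneck(0.05),
                  scenario_zigzag())) {
    tmp <- tempfile()
    write_scenario(sp, tmp)
    back <- read_scenario(tmp)
    expect_equal(back, sp)
    unlink(tmp)
  }
})

test_that("predefined scenarios match their stated parameters", {
  sc <- predefined_scenarios()
  expect_named(sc, c("clean_split", "split_with_migration", "archaic",
                     "archaic_bottleneck", "zigzag"))
  zz <- sc$zigzag
  expect_equal(range(zz$demes$pop1$N), c(3000, 30000))
  expect_equal(zz$rho, 0.3e-8)
  mig <- Filter(function(e) e$type == "migration",
                sc$split_with_migration$events)[[1]]
  # per-direction time-integral of the window is 0.5
  expect_equal(mig$rate * (mig$end_gen - mig$start_gen), 0.5)
  bn <- sc$archaic_bottleneck$demes$pop1
  expect_equal(bn$N, c(20000, 20000 / 30, 20000))
})

test_that("archaic exact rates agree with msprime pairwise coalescence times", {
  g <- make_time_grid("1*2+25*1+1*2+1*3")
  sp <- scenario_archaic(alpha = 0.05)
  tab <- exact_coal_rates(sp, g)
  mu <- g$mu
  b <- segment_boundaries_gen(g)
  # empirical tMRCA histograms for the three start states via msprime,
  # single non-recombining locus, many replicate pairs
  script <- 'import msprime, sys, json
import numpy as np
dem = msprime.Demography()
for p in ["pop1","pop2","archaic"]:
    dem.add_population(name=p, initial_size=20000)
gen = 1000.0/29.0
dem.add_mass_migration(time=30*gen, source="pop1", dest="archaic", proportion=0.05)
dem.add_mass_migration(time=75*gen, source="pop2", dest="pop1", proportion=1.0)
dem.add_mass_migration(time=1000*gen, source="archaic", dest="pop1", proportion=1.0)
dem.sort_events()
out = {}
for tag, samp in [("S11", {"pop1": 1}), ("S12", [msprime.SampleSet(1, population="pop1", ploidy=1), msprime.SampleSet(1, population="pop2", ploidy=1)]), ("S22", {"pop2": 1})]:
    reps = msprime.sim_ancestry(samples=samp, demography=dem, ploidy=2,
                                num_replicates=20000, random_seed=17)
    ts_times = [next(t.trees()).time(t.first().root) for t in reps]
    out[tag] = ts_times
json.dump({k: v for k, v in out.items()}, open(sys.argv[1], "w"))'
  pyfile <- tempfile(fileext = ".py"); jfile <- tempfile(fileext = ".json")
  writeLines(script, pyfile)
  st <- system2(Sys.which("python"), c(pyfile, jfile), stdout = TRUE,
                stderr = TRUE)
  skip_if(!file.exists(jfile), "msprime oracle unavailable")
  times <- jsonlite::fromJSON(jfile)
  breaks <- c(b, Inf)
  for (s0 in c("S11", "S12", "S22")) {
    emp <- as.numeric(table(cut(times[[s0]], breaks))) / length(times[[s0]])
    S <- msmc_tmrca_survival(tab, s0, b, mu)
    model <- c(S[-length(S)] - S[-1], S[length(S)])
    n <- length(times[[s0]])
    se <- sqrt(pmax(emp * (1 - emp), 1e-6) / n)
    expect_true(all(abs(model - emp) < 4 * se + 2e-3),
                label = paste("histogram agreement for", s0))
  }
  unlink(c(pyfile, jfile))
})

test_that("events beyond the grid horizon are rejected", {
  g <- make_time_grid("4*1")
  expect_error(exact_coal_rates(scenario_archaic(0.05, Ta_kya = 5000), g),
               "horizon")
})
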
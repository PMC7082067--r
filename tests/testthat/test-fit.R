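grid28 <- make_time_grid("1*2+25*1+1*2+1*3")
mu <- grid28$mu

# three-rate table implied by a known parameter set
table_from_params <- function(par) im_implied_coalrates(par)

test_that("chi-square vanishes for a perfect model without penalties", {
  par <- im_params(grid28, 20000, 20000, 1e-5)
  tab <- table_from_params(par)
  cfg <- fit_config(beta1 = 0, beta2 = 0, residual = "mass")
  # the table stores segment-average hazards, which reproduce the model's
  # masses exactly
  expect_lt(chi_square(par, tab, cfg), 1e-14)
})

test_that("penalties vanish for equal sizes and zero migration", {
  par <- im_params(grid28, 15000, 15000, 0)
  tab <- table_from_params(im_params(grid28, 20000, 25000, 1e-5))
  c0 <- chi_square(par, tab, fit_config(beta1 = 0, beta2 = 0))
  c1 <- chi_square(par, tab, fit_config(beta1 = 1e-2, beta2 = 1e-2))
  expect_equal(c0, c1)
})

test_that("chi-square matches an independent plain-R transcription", {
  set.seed(17)
  par <- im_params(grid28,
                   N1 = runif(28, 5000, 50000),
                   N2 = runif(28, 5000, 50000),
                   m = runif(28, 0, 1e-4))
  tab <- table_from_params(im_params(grid28,
                                     N1 = runif(28, 5000, 50000),
                                     N2 = runif(28, 5000, 50000),
                                     m = runif(28, 0, 1e-4)))
  cfg <- fit_config(beta1 = 3e-7, beta2 = 2e-5, residual = "density")
  got <- chi_square(par, tab, cfg)

  # independent transcription: propagate the three start-state occupancy
  # vectors with expm() computed by eigen-free series summation, densities
  # at segment right boundaries, penalties as written
  b <- segment_boundaries_gen(grid28)
  K <- 28
  w <- c(diff(b), b[K] - b[K - 1])
  series_expm <- function(M) {
    # scaling and squaring with a plain Taylor series
    nsq <- max(0, ceiling(log2(max(1, max(abs(M)) * 8))))
    Ms <- M / 2^nsq
    S <- diag(nrow(M)); term <- diag(nrow(M))
    for (k in 1:30) {
      term <- term %*% Ms / k
      S <- S + term
    }
    for (i in seq_len(nsq)) S <- S %*% S
    S
  }
  gen <- function(m, N1, N2) {
    Q <- matrix(0, 4, 4)
    Q[1, 4] <- 1 / (2 * N1); Q[3, 4] <- 1 / (2 * N2)
    Q[2, 1] <- m / 2; Q[2, 3] <- m / 2
    diag(Q) <- -rowSums(Q)
    Q
  }
  S_data <- sapply(c("S11", "S12", "S22"), function(s)
    msmc_tmrca_survival(tab, s, c(b[-1], b[K] + w[K]), mu))
  lam_data <- cbind(tab$lambda_00, tab$lambda_01, tab$lambda_11) * mu
  occ <- diag(1, 3, 4)
  expected <- 0
  for (i in 1:K) {
    occ <- occ %*% series_expm(gen(par$m[i], par$N1[i], par$N2[i]) * w[i])
    for (s in 1:3) {
      pim <- occ[s, 1] / (2 * par$N1[i]) + occ[s, 3] / (2 * par$N2[i])
      pm <- lam_data[i, s] * S_data[i, s]
      expected <- expected + (pim - pm)^2 / max(pm, cfg$dens_floor)
    }
    expected <- expected + cfg$beta1 * par$m[i] * w[i] +
      cfg$beta2 * ((par$N1[i] - par$N2[i]) / (par$N1[i] + par$N2[i]))^2
  }
  expect_equal(got, unname(expected), tolerance = 1e-10)
})

test_that("self-consistency: a model-generated target is recovered", {
  b <- segment_boundaries_gen(grid28)
  w <- c(diff(b), b[28] - b[27])
  m_true <- rep(0, 28)
  m_true[3] <- 2 / w[3]
  m_true[10] <- 4 / w[10]
  truth <- im_params(grid28, N1 = 18000, N2 = 26000, m = m_true)
  tab <- table_from_params(truth)
  fit <- im_fit(tab)
  expect_equal(fit$status, "converged")
  expect_lte(fit$chi2, fit$chi2_init + 1e-12)
  # recovered M(t) matches the generating model closely where identified
  Mfit <- cumulative_migration(fit$params)
  Mtrue <- cumulative_migration(truth)
  keep <- Mtrue < 0.999
  expect_lt(max(abs(Mfit[keep] - Mtrue[keep])), 0.05)
  # sizes recovered within 5% where they are identified: outside the
  # pulse segments (where residual mass can trade off against m within
  # the segment) and before the deep tail where the size-difference
  # penalty dominates the vanishing residual weight
  idx <- setdiff(2:20, c(3L, 10L))
  expect_lt(max(abs(coef(fit)[idx, "N1"] / 18000 - 1)), 0.05)
  expect_lt(max(abs(coef(fit)[idx, "N2"] / 26000 - 1)), 0.05)
})

test_that("clean-split target yields one dominant pulse at the split time", {
  tab <- exact_coal_rates(scenario_clean_split(75), grid28)
  fit <- im_fit(tab)
  pl <- detect_pulses(fit)
  expect_equal(nrow(pl), 1L)
  med <- m_percentiles(fit, 0.5)
  Tg <- years_to_generations(75e3)
  b <- segment_boundaries_gen(grid28)
  iT <- findInterval(Tg, b)
  # median within one grid segment of the split time
  expect_gte(med, b[max(1, iT - 1)])
  expect_lte(med, b[min(28, iT + 2)])
})

test_that("relative cross coalescence rate has its limiting values", {
  b <- grid28$segment_left_scaled
  tab0 <- rate_table(b, c(b[-1], Inf), cbind(rep(2000, 28), rep(0, 28), rep(2000, 28)))
  expect_equal(rccr(tab0), rep(0, 28))
  tab1 <- rate_table(b, c(b[-1], Inf), matrix(1500, 28, 3))
  expect_equal(rccr(tab1), rep(1, 28))
})

test_that("reported migration is masked after M reaches the cut-off", {
  tab <- exact_coal_rates(scenario_clean_split(75), grid28)
  fit <- im_fit(tab)
  df <- as.data.frame(fit)
  over <- which(df$M >= fit$config$M_report_cap)
  if (length(over) > 1L) expect_true(all(is.na(df$m[over[-1]])))
  expect_true(all(diff(df$M) >= -1e-12))
})

test_that("stronger migration regularization never increases total migration", {
  tab <- exact_coal_rates(scenario_clean_split(75), grid28)
  w <- imtracer:::segment_widths_gen(grid28)
  totals <- vapply(c(1e-8, 1e-6, 1e-4), function(b1) {
    f <- im_fit(tab, config = fit_config(beta1 = b1))
    sum(coef(f)[, "m"] * w)
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-6 + 0.05 * abs(totals[-3])))
})

test_that("fit is invariant to a joint rescaling of time and rates", {
  tab <- exact_coal_rates(scenario_clean_split(75), grid28)
  fit1 <- im_fit(tab, mu = mu)
  # halve mu: scaled times halve, scaled rates double; generations identical
  tab2 <- tab
  tab2$left_time_boundary <- tab$left_time_boundary / 2
  tab2$right_time_boundary <- tab$right_time_boundary / 2
  for (cn in c("lambda_00", "lambda_01", "lambda_11"))
    tab2[[cn]] <- tab[[cn]] * 2
  fit2 <- im_fit(tab2, mu = mu / 2)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-4)
  expect_equal(fit2$M, fit1$M, tolerance = 1e-6)
})

test_that("grid mismatch between params and target is an error", {
  tab <- exact_coal_rates(scenario_clean_split(75), grid28)
  other <- im_params(make_time_grid("8*1"), 2e4, 2e4, 0)
  expect_error(chi_square(other, tab), "grid")
})
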
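test_that("unbiased samples reproduce direct Boltzmann inversion", {
  set.seed(10)
  x <- rbeta(2e5, 2, 3)  # non-trivial density on [0, 1]
  w <- window_from_positions(x, center = 0, force_constant = 0)
  cfg <- wham_config(0, 1, n_bins = 50, anchor_region = c(0.4, 0.6))
  pmf <- solve_wham(w, thermo298, cfg)
  edges <- seq(0, 1, length.out = 51)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = 50)
  g_direct <- -thermo298$kT * log(h / sum(h))
  in_anchor <- pmf$bin_centers >= 0.4 & pmf$bin_centers <= 0.6
  g_direct <- g_direct - mean(g_direct[in_anchor])
  expect_equal(pmf$free_energy, g_direct, tolerance = 1e-9)
})

test_that("uniform unbiased sampling yields a flat free energy", {
  set.seed(11)
  w <- window_from_positions(runif(3e5), force_constant = 0)
  cfg <- wham_config(0, 1, n_bins = 40, anchor_region = c(0, 1))
  pmf <- solve_wham(w, thermo298, cfg)
  expect_lt(diff(range(pmf$free_energy)), 0.3 * thermo298$kT)
})

test_that("WHAM removes a harmonic bias from exact Boltzmann samples", {
  ## flat landscape, bias K = 1000: biased density is N(c, kT/K)
  set.seed(12)
  k <- 1000
  sdv <- sqrt(thermo298$kT / k)
  wins <- lapply(c(-0.1, 0, 0.1), function(c0)
    umbrella_window(c0, k, 0.001 * (1:2e5), rnorm(2e5, c0, sdv)))
  cfg <- wham_config(-0.2, 0.2, n_bins = 80, anchor_region = c(-0.2, 0.2))
  pmf <- solve_wham(wins, thermo298, cfg)
  ## true landscape is flat: recovered G within 0.05 kT over the well region
  core <- abs(pmf$bin_centers) <= 0.12
  g <- pmf$free_energy[core]
  expect_lt(max(abs(g - mean(g))), 0.05 * thermo298$kT)
})

test_that("translating centers and samples translates the profile", {
  set.seed(13)
  k <- 500
  sdv <- sqrt(thermo298$kT / k)
  base <- lapply(c(-0.1, 0.05), function(c0) rnorm(5e4, c0, sdv))
  mk <- function(shift) lapply(seq_along(base), function(i)
    umbrella_window(c(-0.1, 0.05)[i] + shift, k, 0.001 * (1:5e4),
                    base[[i]] + shift))
  p0 <- solve_wham(mk(0), thermo298,
                   wham_config(-0.3, 0.3, 60, anchor_region = c(-0.3, 0.3)))
  p1 <- solve_wham(mk(0.7), thermo298,
                   wham_config(0.4, 1.0, 60, anchor_region = c(0.4, 1.0)))
  expect_equal(p1$bin_centers, p0$bin_centers + 0.7, tolerance = 1e-12)
  expect_equal(p1$free_energy, p0$free_energy, tolerance = 1e-9)
})

test_that("window offsets satisfy the converged self-consistency", {
  sch <- build_scheme(list(scheme_region(-0.4, 0.4, 0.2, 800)))
  reps <- simulate_scheme(double_well_landscape(), sch, 1, thermo298,
                          dt = 1e-4, n_steps = 2e5, save_every = 10L,
                          seed = 14)
  cfg <- wham_config(-0.5, 0.5, n_bins = 80, anchor_region = c(0.3, 0.5))
  pmf <- solve_wham(reps$replicates[[1L]], thermo298, cfg)
  expect_lt(attr(pmf, "residual"), cfg$tolerance)
  expect_length(attr(pmf, "window_offsets"), 5L)
  expect_equal(attr(pmf, "window_offsets")[1L], 0)
})

test_that("pooled equals per-replicate for one or duplicated replicates", {
  sch <- build_scheme(list(scheme_region(-0.2, 0.2, 0.2, 800)))
  reps1 <- simulate_scheme(flat_landscape(), sch, 1, thermo298,
                           dt = 1e-4, n_steps = 1e5, save_every = 10L,
                           seed = 15)
  cfg <- wham_config(-0.3, 0.3, n_bins = 50, anchor_region = c(-0.3, 0.3))
  r1 <- pooled_and_per_replicate_pmfs(reps1, thermo298, cfg)
  expect_equal(r1$pooled$free_energy, r1$per_replicate[[1L]]$free_energy,
               tolerance = 1e-9)
  ## five identical replicates: pooling changes nothing
  reps5 <- replicate_set(rep(reps1$replicates, 5L), 0)
  r5 <- pooled_and_per_replicate_pmfs(reps5, thermo298, cfg)
  for (p in r5$per_replicate)
    expect_equal(r5$pooled$free_energy, p$free_energy, tolerance = 1e-9)
})

test_that("pooled profile lies within the replicate envelope", {
  sch <- build_scheme(list(scheme_region(-0.4, 0.4, 0.2, 800)))
  reps <- simulate_scheme(double_well_landscape(), sch, 5, thermo298,
                          dt = 1e-4, n_steps = 1e5, save_every = 10L,
                          seed = 16)
  cfg <- wham_config(-0.5, 0.5, n_bins = 60, anchor_region = c(0.3, 0.5))
  r <- pooled_and_per_replicate_pmfs(reps, thermo298, cfg)
  per <- sapply(r$per_replicate, `[[`, "free_energy")
  ok <- stats::complete.cases(per) & !is.na(r$pooled$free_energy)
  inside <- r$pooled$free_energy[ok] >= apply(per[ok, ], 1, min) - 1e-9 &
    r$pooled$free_energy[ok] <= apply(per[ok, ], 1, max) + 1e-9
  expect_gte(mean(inside), 0.95)
})

test_that("empty windows and non-convergence raise informative errors", {
  w <- window_from_positions(rnorm(200, 5), center = 5)
  cfg <- wham_config(0, 1, n_bins = 20, anchor_region = c(0, 1))
  expect_error(solve_wham(w, thermo298, cfg), "insufficient sampling")
  ## several overlapping windows cannot self-consist in two iterations
  set.seed(17)
  wins <- lapply(seq(0.1, 0.9, by = 0.1), function(c0)
    umbrella_window(c0, 300, 0.001 * (1:5000),
                    rnorm(5000, c0, sqrt(thermo298$kT / 300))))
  cfg2 <- wham_config(0, 1, n_bins = 20, max_iter = 2L,
                      anchor_region = c(0, 1))
  expect_error(solve_wham(wins, thermo298, cfg2), "did not converge")
})
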
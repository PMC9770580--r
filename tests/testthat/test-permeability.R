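## helper: profile + constant-D diffusion pair on a grid
const_d_profile <- function(z, g_kj, d = 0.5,
                            frame = "bilayer_center") {
  pmf <- pmf_profile(z, g_kj, units = "kJ/mol", reference_frame = frame)
  dp <- pmfperm:::new_diffusion_profile(range(z), rep(d, 2),
                                        rep(d, 2), c(1, 1))
  list(pmf = pmf, dp = dp)
}

test_that("zero barrier and constant D give R = 1/D and P = D/L", {
  z <- seq(0, 2, length.out = 201)
  pr <- const_d_profile(z, rep(0, 201), d = 0.4)
  rp <- resistance_profile(pr$pmf, pr$dp, thermo298)
  expect_equal(rp$resistance, rep(1 / (0.4 * 1e-5), 201))
  P <- permeability(rp)
  expect_equal(P, 0.4 * 1e-5 / (2 * 1e-7), tolerance = 1e-12)
})

test_that("raising one bin by kT ln 2 doubles its resistance", {
  z <- seq(0, 1, length.out = 101)
  g <- rep(0, 101)
  g[51] <- thermo298$kT * log(2)
  pr <- const_d_profile(z, g)
  rp <- resistance_profile(pr$pmf, pr$dp, thermo298)
  expect_equal(rp$resistance[51] / rp$resistance[50], 2, tolerance = 1e-12)
})

test_that("a square barrier matches the closed-form permeability", {
  L <- 2; w <- 0.5; B <- 2 * thermo298$kT; d <- 0.3
  z <- seq(0, L, length.out = 4001)
  g <- ifelse(z > 0.75 & z < 0.75 + w, B, 0)
  pr <- const_d_profile(z, g, d = d)
  P <- permeability(resistance_profile(pr$pmf, pr$dp, thermo298))
  P_closed <- (d * 1e-5) /
    ((w * exp(thermo298$beta * B) + (L - w)) * 1e-7)
  expect_equal(P, P_closed, tolerance = 1e-3)
})

test_that("quadrature is converged: halving the spacing moves P < 0.1%", {
  mk <- function(n) {
    z <- seq(-2, 2, length.out = n)
    g <- 12 * exp(-z^2 / 0.5) - 8 * exp(-(z + 1.5)^2 / 0.3)
    pr <- const_d_profile(z, g)
    permeability(resistance_profile(pr$pmf, pr$dp, thermo298))
  }
  expect_lt(abs(mk(801) / mk(401) - 1), 1e-3)
})

test_that("resistance peaks at the PMF maximum when D is constant", {
  z <- seq(-2, 1.6, length.out = 181)
  g <- 12 * exp(-z^2 / 0.1) - 16 * exp(-(z + 2)^2 / 0.5)
  pr <- const_d_profile(z, g)
  rp <- resistance_profile(pr$pmf, pr$dp, thermo298)
  expect_equal(which.max(rp$resistance), which.max(g))
})

test_that("masked interior bins and non-positive D are rejected", {
  z <- seq(0, 1, length.out = 51)
  g <- rep(0, 51); g[25] <- NA
  pmf <- pmf_profile(z, g, units = "kJ/mol")
  dp <- pmfperm:::new_diffusion_profile(c(0, 1), c(0.5, 0.5), c(0.5, 0.5),
                                        c(1, 1))
  expect_error(resistance_profile(pmf, dp, thermo298),
               "incomplete profile")
})

test_that("mirroring reflects the monolayer profile about its center end", {
  z <- seq(-2, 1.6, by = 0.1)
  g <- 12 * exp(-z^2 / 0.1) - 16 * exp(-(z + 2)^2 / 0.5)
  pmf <- pmf_profile(z, g, units = "kJ/mol",
                     reference_frame = "closest_p_layer")
  full <- mirror_monolayer_profile(pmf)
  expect_equal(length(full$bin_centers), 2L * length(z) - 1L)
  expect_equal(min(full$bin_centers), 2 * (-2) - 1.6)
  ## reflection identity G(-2 - x) = G(-2 + x)
  for (x in c(0.3, 1.0, 2.5)) {
    gl <- full$free_energy[which.min(abs(full$bin_centers - (-2 - x)))]
    gr <- full$free_energy[which.min(abs(full$bin_centers - (-2 + x)))]
    expect_equal(gl, gr, tolerance = 1e-12)
  }
  ## idempotent once tagged bilayer-symmetric
  expect_identical(mirror_monolayer_profile(full), full)
  expect_error(mirror_monolayer_profile(
    pmf_profile(z, g, units = "kJ/mol")), "invalid frame")
})

test_that("mirrored permeability equals an explicitly symmetric build", {
  z <- seq(-2, 1.6, by = 0.02)
  g <- 12 * exp(-z^2 / 0.1) - 16 * exp(-(z + 2)^2 / 0.5)
  pmf <- pmf_profile(z, g, units = "kJ/mol",
                     reference_frame = "closest_p_layer")
  full <- mirror_monolayer_profile(pmf)
  dp <- pmfperm:::new_diffusion_profile(c(-6, 2), c(0.5, 0.5),
                                        c(0.5, 0.5), c(1, 1))
  P_mirror <- permeability(resistance_profile(full, dp, thermo298))
  z2 <- c(2 * (-2) - rev(z[-1]), z)
  g2 <- c(rev(g[-1]), g)
  sym <- pmf_profile(z2, g2, units = "kJ/mol",
                     reference_frame = "closest_p_layer")
  P_sym <- permeability(resistance_profile(sym, dp, thermo298))
  expect_equal(P_mirror, P_sym, tolerance = 1e-12)
})

test_that("entry and exit barriers match a constructed two-level profile", {
  ## interface peak of 2.9 kcal/mol, central minimum of -4.2 kcal/mol
  z <- seq(-2, 1.6, by = 0.02)
  g_kcal <- 2.9 * exp(-(z / 0.25)^2) - 4.2 * exp(-((z + 2) / 0.5)^2)
  pmf <- pmf_profile(z, g_kcal, units = "kcal/mol")
  b <- barriers(pmf, thermo298)
  expect_equal(b$dg_entry, 2.9, tolerance = 1e-3)
  expect_equal(b$dg_exit, 7.1, tolerance = 1e-3)
  expect_equal(b$z_interface, 0, tolerance = 0.02)
  expect_equal(b$z_min, -2, tolerance = 0.02)
})

test_that("a profile decaying from the bulk plateau has zero entry barrier", {
  z <- seq(-2, 1.6, by = 0.02)
  g <- ifelse(z < 0, 8 * z, 0)  # plateau at 0, falls toward the center
  pmf <- pmf_profile(z, g, units = "kJ/mol")
  b <- barriers(pmf, thermo298)
  expect_equal(b$dg_entry, 0, tolerance = 1e-9)
  expect_equal(b$dg_exit, convert_energy(16, "kJ/mol", "kcal/mol"),
               tolerance = 1e-9)
})

test_that("barriers are stable under small non-peak perturbations", {
  set.seed(30)
  z <- seq(-2, 1.6, by = 0.02)
  g <- convert_energy(2.9 * exp(-(z / 0.25)^2) -
                        4.2 * exp(-((z + 2) / 0.5)^2),
                      "kcal/mol", "kJ/mol")
  b0 <- barriers(pmf_profile(z, g, units = "kJ/mol"), thermo298)
  gp <- g
  touch <- abs(z) > 0.1 & abs(z + 2) > 0.1
  gp[touch] <- gp[touch] + runif(sum(touch), -0.01, 0.01) * thermo298$kT
  b1 <- barriers(pmf_profile(z, gp, units = "kJ/mol"), thermo298)
  tol_kcal <- convert_energy(0.02 * thermo298$kT, "kJ/mol", "kcal/mol")
  expect_lt(abs(b1$dg_entry - b0$dg_entry), tol_kcal)
  expect_lt(abs(b1$dg_exit - b0$dg_exit), tol_kcal)
  expect_error(barriers(pmf_profile(z, rep(0, length(z)),
                                    units = "kJ/mol"), thermo298),
               "flat profile")
})

test_that("permeability is gauge invariant and barrier monotonic", {
  z <- seq(-2, 2, length.out = 401)
  g <- 10 * exp(-z^2 / 0.2)
  pr <- const_d_profile(z, g)
  P0 <- permeability(resistance_profile(pr$pmf, pr$dp, thermo298))
  ## shifting G by a constant and re-anchoring changes nothing
  pr2 <- const_d_profile(z, g + 7)
  pr2$pmf$free_energy <- pr2$pmf$free_energy - 7
  P2 <- permeability(resistance_profile(pr2$pmf, pr2$dp, thermo298))
  expect_equal(P2, P0, tolerance = 1e-12)
  ## raising any single bin's G lowers P
  g3 <- g; g3[200] <- g3[200] + 2
  pr3 <- const_d_profile(z, g3)
  expect_lt(permeability(resistance_profile(pr3$pmf, pr3$dp, thermo298)),
            P0)
  ## for constant D, ln P reduces to -ln of the Boltzmann-weighted length
  gfun <- splinefun(z, g)
  intg <- integrate(function(x) exp(thermo298$beta * gfun(x)), -2, 2,
                    rel.tol = 1e-10)$value
  P_closed <- 0.5 * 1e-5 / (intg * 1e-7)
  expect_equal(log(P0), log(P_closed), tolerance = 5e-4)
})

test_that("analyze_system handles duplicate and single replicates", {
  sch <- build_scheme(list(scheme_region(-0.6, 0.6, 0.1, 800)))
  ls <- landscape(data.frame(z = c(-0.8, -0.4, 0, 0.4, 0.8),
                             value = c(0, 1.5, 6, 1.5, 0)),
                  data.frame(z = c(-0.8, 0.8), value = c(0.4, 0.4)),
                  z_range = c(-1, 1))
  reps1 <- simulate_scheme(ls, sch, 1, thermo298, dt = 1e-4,
                           n_steps = 2e5, save_every = 10L, seed = 31)
  cfg <- wham_config(-0.6, 0.6, n_bins = 80,
                     anchor_region = c(0.45, 0.6))
  single <- analyze_system(reps1, thermo298, cfg)
  expect_true(all(is.na(single$standard_errors)))
  expect_gt(single$permeability, 0)
  ## duplicated replicates: every leave-one-out subset is identical
  reps3 <- replicate_set(rep(reps1$replicates, 3L), 0)
  dup <- analyze_system(reps3, thermo298, cfg)
  expect_equal(unname(dup$standard_errors), rep(0, 3), tolerance = 1e-9)
  expect_equal(dup$permeability, single$permeability, tolerance = 1e-9)
})
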
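test_that("a fixed seed reproduces trajectories exactly", {
  w1 <- ou_window(seed = 50, n_steps = 1e5)
  w2 <- ou_window(seed = 50, n_steps = 1e5)
  w3 <- ou_window(seed = 51, n_steps = 1e5)
  expect_identical(w1$positions, w2$positions)
  expect_false(identical(w1$positions, w3$positions))
  ## the generator does not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(ou_window(seed = 50, n_steps = 1e4))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("simulate_scheme derives distinct per-window seeds", {
  sch <- build_scheme(list(scheme_region(0, 0.1, 0.1, 500)))
  reps <- simulate_scheme(flat_landscape(), sch, 3, thermo298,
                          dt = 1e-4, n_steps = 1e4, save_every = 10L,
                          seed = 52)
  series <- unlist(lapply(reps$replicates, function(r)
    lapply(r, function(w) paste(head(w$positions, 50), collapse = ","))))
  expect_length(unique(series), 6L)
  seeds <- c(outer(1:3, 1:2, function(r, w) derive_window_seed(52, r, w)))
  expect_length(unique(seeds), 6L)
  reps2 <- simulate_scheme(flat_landscape(), sch, 3, thermo298,
                           dt = 1e-4, n_steps = 1e4, save_every = 10L,
                           seed = 52)
  expect_identical(reps$replicates[[2L]][[1L]]$positions,
                   reps2$replicates[[2L]][[1L]]$positions)
})

test_that("free diffusion has increment variance 2 D dt", {
  w <- simulate_window(flat_landscape(0.5, z_range = c(-50, 50)), 0, 0,
                       thermo298, dt = 1e-4, n_steps = 1e6,
                       save_every = 10L, seed = 53)
  inc <- diff(w$positions)
  expect_equal(var(inc), 2 * 0.5 * 1e-3, tolerance = 0.05)
})

test_that("the harmonic stationary variance is kT/K", {
  w <- ou_window(kf = 1000, d = 0.5, dt = 1e-5, n_steps = 2e7,
                 save_every = 100L, seed = 54)
  expect_equal(var(w$positions), thermo298$kT / 1000, tolerance = 0.03)
})

test_that("instability and divergence are caught", {
  ## a steep landscape violates the drift-vs-noise heuristic at large dt
  steep <- landscape(data.frame(z = c(-1, 0.9, 1), value = c(0, 0, 4000)),
                     data.frame(z = c(-1, 1), value = c(0.5, 0.5)),
                     z_range = c(-1, 1))
  expect_error(simulate_window(steep, 0.95, 0, thermo298, dt = 1e-3,
                               n_steps = 100, save_every = 1L, seed = 55),
               "unstable")
  ## free diffusion on a tiny range walks out of it
  tiny <- flat_landscape(5, z_range = c(-0.05, 0.05))
  expect_error(simulate_window(tiny, 0, 0, thermo298, dt = 1e-3,
                               n_steps = 1e5, save_every = 10L, seed = 56),
               "left the landscape")
})

test_that("the unbiased stationary density is Boltzmann (chi-squared)", {
  ## position-dependent D (five-fold range): validates the spurious-drift
  ## term, since without it the density acquires a 1/D(z) factor
  ## fine step: the chi-squared check is sensitive to the O(dt) Euler bias
  ls <- walled_landscape()
  w <- simulate_window(ls, 0, 0, thermo298, dt = 5e-5, n_steps = 8e7,
                       save_every = 40000L, seed = 57)
  x <- w$positions
  edges <- seq(-0.75, 0.75, length.out = 13)
  obs <- tabulate(findInterval(x[x >= -0.75 & x <= 0.75], edges,
                               all.inside = TRUE), nbins = 12)
  pr <- vapply(1:12, function(i) {
    zz <- seq(edges[i], edges[i + 1], length.out = 64)
    mean(exp(-thermo298$beta * ls$g(zz))) * (edges[i + 1] - edges[i])
  }, 0)
  pr <- pr / sum(pr)
  ct <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(ct$p.value, 0.01)
  ## dropping the spurious drift visibly skews the density toward low D
  w0 <- simulate_window(ls, 0, 0, thermo298, dt = 5e-5, n_steps = 8e7,
                        save_every = 40000L, seed = 57,
                        spurious_drift = FALSE)
  expect_lt(mean(w0$positions), mean(x) - 0.05)
})

test_that("membrane frames are deterministic and honour the construction", {
  fr <- flat_bilayer_frame(n = 64, half = 2.0, seed = 60)
  fr2 <- flat_bilayer_frame(n = 64, half = 2.0, seed = 60)
  expect_identical(fr$p_atoms_xyz, fr2$p_atoms_xyz)
  expect_equal(local_thickness(fr)$half_thickness, 2.0)
  expect_error(make_membrane_frames(200, 2.0, probe_path = list(c(1, 1, 5)),
                                    box = c(4, 4, 10)),
               "packing")
})

test_that("a -0.3 nm depression reduces the local thickness", {
  box <- c(8, 8, 12)
  probe <- c(4, 4, 9.2)  # above the upper leaflet
  dep <- flat_bilayer_frame(n = 100, half = 2.0, box = box, probe = probe,
                            deformation = list(amplitude = -0.3,
                                               radius = 1.0), seed = 61)
  res <- local_thickness(dep)
  expect_lt(res$half_thickness, 2.0)
  expect_gt(res$half_thickness, 2.0 - 0.3 - 1e-9)
  ## the recovered value equals the mean bump of the in-cutoff atoms
  flatf <- flat_bilayer_frame(n = 100, half = 2.0, box = box,
                              probe = probe, seed = 61)
  lf <- assign_leaflets(dep)
  d <- pmfperm:::.xy_min_image_dist(dep)
  loc <- intersect(lf$upper, which(d <= 1.0))
  expected <- mean(dep$p_atoms_xyz[loc, 3]) - res$membrane_center_z
  expect_equal(res$half_thickness, expected, tolerance = 1e-12)
  expect_equal(local_thickness(flatf)$half_thickness, 2.0)
})

test_that("thickness is unbiased under z-noise", {
  frames <- make_membrane_frames(100, 2.0, z_noise = 0.05,
                                 probe_path = rep(list(c(4, 4, 9)), 60),
                                 box = c(8, 8, 12), seed = 62)
  th <- vapply(frames, function(f) local_thickness(f)$half_thickness, 0)
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 2.0), 2 * se + 1e-3)
})
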
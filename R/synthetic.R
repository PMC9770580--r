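#' Ground-truth 1-D landscape for synthetic umbrella data
#'
#' A free-energy function G(z) (kJ/mol) and a positive diffusion function
#' D(z) (nm^2/ns), each interpolated from control points by natural cubic
#' splines (D is splined on the log scale, guaranteeing positivity).
#' Outside the control range both splines extrapolate linearly.
#'
#' @param free_energy data frame (or 2-column matrix) of control points:
#'   z (nm), G (kJ/mol).
#' @param diffusion control points: z (nm), D (nm^2/ns), all D > 0.
#' @param z_range length-2 interval (nm) on which the landscape is used.
#' @return an object of class \code{"landscape"} with spline functions
#'   \code{g}, \code{dg} (dG/dz), \code{d}, \code{dd} (dD/dz) and
#'   \code{z_range}.
#' @export
landscape <- function(free_energy, diffusion, z_range) {
  fe <- as.data.frame(free_energy)
  di <- as.data.frame(diffusion)
  names(fe) <- c("z", "value")[seq_len(ncol(fe))]
  names(di) <- c("z", "value")[seq_len(ncol(di))]
  stopifnot(nrow(fe) >= 2L, nrow(di) >= 2L, length(z_range) == 2L,
            z_range[1] < z_range[2])
  if (any(di$value <= 0)) stop("diffusion must be positive", call. = FALSE)
  g_sp <- splinefun(fe$z, fe$value, method = "natural")
  logd_sp <- splinefun(di$z, log(di$value), method = "natural")
  zz <- seq(z_range[1], z_range[2], length.out = 512L)
  if (any(!is.finite(g_sp(zz))) || any(!is.finite(exp(logd_sp(zz)))))
    stop("landscape not finite over z_range", call. = FALSE)
  structure(list(
    g = g_sp,
    dg = function(z) g_sp(z, deriv = 1L),
    d = function(z) exp(logd_sp(z)),
    dd = function(z) exp(logd_sp(z)) * logd_sp(z, deriv = 1L),
    z_range = as.numeric(z_range),
    control = list(free_energy = fe, diffusion = di)),
    class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "Landscape on [%.2f, %.2f] nm: %d G control points, %d D control points\n",
    x$z_range[1], x$z_range[2], nrow(x$control$free_energy),
    nrow(x$control$diffusion)))
  invisible(x)
}

#' Membrane-like landscape preset
#'
#' A monolayer-referenced (closest-P-layer) free-energy profile emulating a
#' hydrophobic probe crossing a phospholipid leaflet: bulk water at zero,
#' an interface barrier of about 3 kcal/mol at the phosphate plane (z = 0)
#' and a central well of about -4 kcal/mol at the membrane center
#' (z = -2 nm), with the diffusion coefficient dropping roughly five-fold
#' from 0.5 nm^2/ns in water to 0.1 nm^2/ns inside the membrane.  The
#' profile is built symmetric about z = -2 so that the generated data obey
#' the bilayer symmetry the mirroring step assumes.
#'
#' @return a \code{\link{landscape}} on z in [-3.0, 2.0] nm.
#' @export
membrane_like_landscape <- function() {
  half_g <- data.frame(
    z = c(-2.0, -1.6, -1.2, -0.8, -0.4, 0.0, 0.4, 0.8, 1.2, 1.6, 2.0),
    value = c(-17.6, -16.0, -9.0, -1.0, 7.0, 12.1, 7.5, 2.0, 0.2, 0.0, 0.0))
  ## reflect about z = -2 for bilayer symmetry
  refl <- half_g[-1L, ]
  refl$z <- -4 - refl$z
  g_pts <- rbind(refl[order(refl$z), ], half_g)
  half_d <- data.frame(
    z = c(-2.0, -1.2, -0.4, 0.0, 0.6, 1.2, 2.0),
    value = c(0.10, 0.11, 0.15, 0.20, 0.35, 0.48, 0.50))
  refl_d <- half_d[-1L, ]
  refl_d$z <- -4 - refl_d$z
  d_pts <- rbind(refl_d[order(refl_d$z), ], half_d)
  landscape(g_pts, d_pts, z_range = c(-3.0, 2.0))
}

#' Deterministic per-window seed derivation
#'
#' Documented hash mixing a master seed with replicate and window indices,
#' kept below 2^31 so it is a valid R integer seed:
#' \code{(seed * 48271 + replicate * 30269 + window * 49393) mod (2^31 - 1)}.
#' Any subset of (replicate, window) pairs is therefore reproducible from
#' the master seed alone.
#'
#' @param seed master seed (integer).
#' @param replicate,window 1-based indices.
#' @return a single integer seed.
#' @export
derive_window_seed <- function(seed, replicate, window) {
  m <- 2^31 - 1
  as.integer((as.numeric(seed) %% m * 48271 +
                as.numeric(replicate) * 30269 +
                as.numeric(window) * 49393) %% m)
}

#' Simulate one umbrella window by overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of
#' \deqn{z \leftarrow z + \beta D(z) F(z)\,dt + D'(z)\,dt + \sqrt{2 D(z) dt}\,\eta}
#' with \eqn{F(z) = -dG/dz - K_f (z - z_i)} and \eqn{\eta \sim N(0,1)}.
#' The \eqn{D'(z)} spurious-drift term keeps the stationary density
#' Boltzmann under position-dependent diffusion.  The walk starts at the
#' window center and positions are recorded every \code{save_every} steps.
#' A stability heuristic is enforced at the start point:
#' \eqn{\beta D |F| dt < 0.1 \sqrt{2 D dt}}.
#'
#' @param lscape a \code{\link{landscape}}.
#' @param center umbrella center (nm).
#' @param force_constant K_f (kJ/mol/nm^2); 0 for unbiased dynamics.
#' @param thermo a \code{\link{make_thermo}} object.
#' @param dt integration step (ns).
#' @param n_steps number of integration steps.
#' @param save_every record every this many steps.
#' @param seed integer seed; fixed seed gives identical output.
#' @param label optional window label.
#' @param spurious_drift include the D'(z) dt term (default TRUE; disabling
#'   it is only useful to demonstrate the resulting density bias).
#' @return an \code{\link{umbrella_window}}.
#' @export
simulate_window <- function(lscape, center, force_constant, thermo,
                            dt = 1e-4, n_steps = 1e6, save_every = 10L,
                            seed = 1L, label = NULL,
                            spurious_drift = TRUE) {
  stopifnot(inherits(lscape, "landscape"), inherits(thermo, "thermo_params"))
  if (dt <= 0 || n_steps < save_every)
    stop("invalid dt/n_steps/save_every", call. = FALSE)
  z0 <- center
  D0 <- lscape$d(z0)
  F0 <- -lscape$dg(z0)  # bias force is zero at the center
  if (thermo$beta * D0 * abs(F0) * dt >= 0.1 * sqrt(2 * D0 * dt))
    stop(sprintf(
      "unstable integration: beta*D*|F|*dt = %.3g exceeds 0.1*sqrt(2*D*dt) = %.3g at z0; decrease dt",
      thermo$beta * D0 * abs(F0) * dt, 0.1 * sqrt(2 * D0 * dt)),
      call. = FALSE)
  grid <- seq(lscape$z_range[1], lscape$z_range[2], length.out = 2048L)
  f_land <- -lscape$dg(grid)
  dvals <- lscape$d(grid)
  dprime <- lscape$dd(grid)
  pos <- .with_seed(seed, .simulate_overdamped_cpp(
    z0, center, force_constant, thermo$beta, dt, as.numeric(n_steps),
    as.integer(save_every), grid, f_land, dvals, dprime,
    lscape$z_range[1], lscape$z_range[2], isTRUE(spurious_drift)))
  times <- dt * save_every * seq_along(pos)
  umbrella_window(center, force_constant, times, pos, label = label)
}

#' Simulate a full umbrella scheme with replicates
#'
#' One \code{\link{simulate_window}} run per (window, replicate) pair, with
#' per-window seeds derived from the master seed by
#' \code{\link{derive_window_seed}}.
#'
#' @param lscape a \code{\link{landscape}}.
#' @param scheme an \code{\link{umbrella_scheme}}.
#' @param n_replicates number of replicates.
#' @param thermo a \code{\link{make_thermo}} object.
#' @param dt,n_steps,save_every,spurious_drift per-window integration
#'   settings (see \code{\link{simulate_window}}).
#' @param seed master seed.
#' @param equilibration_time ns tagged on the returned set for downstream
#'   discard (the walk starts at the window center, so the intrinsic
#'   transient is short; default 0).
#' @return a \code{\link{replicate_set}}.
#' @export
simulate_scheme <- function(lscape, scheme, n_replicates, thermo,
                            dt = 1e-4, n_steps = 1e6, save_every = 10L,
                            seed = 1L, equilibration_time = 0,
                            spurious_drift = TRUE) {
  stopifnot(inherits(scheme, "umbrella_scheme"), n_replicates >= 1L)
  reps <- lapply(seq_len(n_replicates), function(r) {
    lapply(seq_len(nrow(scheme$windows)), function(w) {
      simulate_window(lscape, scheme$windows$center[w],
                      scheme$windows$force_constant[w], thermo,
                      dt = dt, n_steps = n_steps, save_every = save_every,
                      seed = derive_window_seed(seed, r, w),
                      label = sprintf("rep%d_win%02d", r, w),
                      spurious_drift = spurious_drift)
    })
  })
  replicate_set(reps, equilibration_time)
}

#' Synthetic membrane coordinate frames
#'
#' Builds phosphorus-atom coordinate snapshots of a planar bilayer: one
#' jittered xy grid per leaflet at z = +/- half_thickness plus Gaussian
#' z-noise, optionally deformed by a Gaussian bump of given amplitude and
#' radius in the probe-side leaflet, centered under the probe xy position
#' (negative amplitude emulates the local depression a probe just outside
#' the phosphate layer imprints; positive amplitude the protrusion when it
#' sits below).  One frame is generated per probe position; output is
#' deterministic under the seed.
#'
#' @param n_lipids_per_leaflet P atoms per leaflet.
#' @param half_thickness leaflet |z| (nm).
#' @param z_noise sd of z jitter (nm).
#' @param deformation \code{NULL} or list/vector with \code{amplitude} (nm)
#'   and \code{radius} (nm).
#' @param probe_path list (or n x 3 matrix) of probe positions (nm).
#' @param box box dimensions (nm); xy area must allow >= 0.6 nm grid
#'   spacing.
#' @param seed integer seed.
#' @return a list of \code{\link{membrane_frame}} objects.
#' @export
make_membrane_frames <- function(n_lipids_per_leaflet, half_thickness,
                                 z_noise = 0, deformation = NULL,
                                 probe_path, box, seed = 1L) {
  if (is.matrix(probe_path))
    probe_path <- lapply(seq_len(nrow(probe_path)),
                         function(i) probe_path[i, ])
  stopifnot(n_lipids_per_leaflet >= 2L, half_thickness > 0,
            length(box) == 3L)
  nx <- ceiling(sqrt(n_lipids_per_leaflet))
  ny <- ceiling(n_lipids_per_leaflet / nx)
  if (box[1] / nx < 0.6 || box[2] / ny < 0.6)
    stop(sprintf(
      "packing error: %d lipids need more than %.1f x %.1f nm of xy area at 0.6 nm spacing",
      n_lipids_per_leaflet, box[1], box[2]), call. = FALSE)
  if (!is.null(deformation)) {
    deformation <- as.list(deformation)
    stopifnot(!is.null(deformation$amplitude), !is.null(deformation$radius),
              deformation$radius > 0)
  }
  gx <- (rep(seq_len(nx), ny)[seq_len(n_lipids_per_leaflet)] - 0.5) *
    box[1] / nx
  gy <- (rep(seq_len(ny), each = nx)[seq_len(n_lipids_per_leaflet)] - 0.5) *
    box[2] / ny
  .with_seed(seed, lapply(probe_path, function(pp) {
    n <- n_lipids_per_leaflet
    ## one xy jitter shared by both leaflets (lipids roughly paired), so a
    ## noise-free flat bilayer has exactly mirrored leaflets
    xy <- cbind(gx + runif(n, -0.05, 0.05),
                gy + runif(n, -0.05, 0.05))
    up <- cbind(xy, box[3] / 2 + half_thickness + rnorm(n, 0, z_noise))
    lo <- cbind(xy, box[3] / 2 - half_thickness + rnorm(n, 0, z_noise))
    if (!is.null(deformation)) {
      side <- if (pp[3] >= box[3] / 2) "up" else "lo"
      tgt <- if (side == "up") up else lo
      dx <- tgt[, 1] - pp[1]; dx <- dx - box[1] * round(dx / box[1])
      dy <- tgt[, 2] - pp[2]; dy <- dy - box[2] * round(dy / box[2])
      bump <- deformation$amplitude *
        exp(-(dx^2 + dy^2) / (2 * deformation$radius^2))
      ## a depression (negative amplitude) moves the upper leaflet down,
      ## i.e. toward the bilayer center; mirror the sense for the lower one
      if (side == "up") tgt[, 3] <- tgt[, 3] + bump
      else tgt[, 3] <- tgt[, 3] - bump
      if (side == "up") up <- tgt else lo <- tgt
    }
    membrane_frame(pp, rbind(up, lo), box)
  }))
}
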
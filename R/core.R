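#' Thermodynamic parameters
#'
#' Bundles the simulation temperature with the derived thermal energy
#' \code{kT = R*T} (kJ/mol) and inverse temperature \code{beta = 1/kT}
#' (mol/kJ), with \code{R = 0.0083144621} kJ/mol/K.
#'
#' @param temperature temperature in kelvin; must be positive.
#' @return an object of class \code{"thermo_params"}: a list with elements
#'   \code{temperature}, \code{kT} and \code{beta}.
#' @examples
#' th <- make_thermo(298.15)
#' th$kT  # 2.478957 kJ/mol
#' @export
make_thermo <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("invalid parameter: temperature must be a single positive number",
         call. = FALSE)
  kT <- .GAS_CONSTANT_KJ * temperature
  structure(list(temperature = temperature, kT = kT, beta = 1 / kT),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Thermodynamic parameters: T = %.2f K, kT = %.6f kJ/mol\n",
              x$temperature, x$kT))
  invisible(x)
}

#' One umbrella-sampling window
#'
#' A harmonically biased window: reference position \code{center} (nm),
#' force constant \code{force_constant} (kJ/mol/nm^2) and the sampled probe
#' reaction-coordinate time series.  Times must be strictly increasing on a
#' uniform grid (relative tolerance 1e-9) and are stored in ns.
#'
#' @param center umbrella reference position z_i (nm).
#' @param force_constant harmonic force constant K_f (kJ/mol/nm^2), positive.
#' @param times sampling times (ns), strictly increasing, uniform step.
#' @param positions probe reaction-coordinate samples (nm), same length.
#' @param label optional window label.
#' @return an object of class \code{"umbrella_window"}.
#' @export
umbrella_window <- function(center, force_constant, times, positions,
                            label = NULL) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(force_constant) || length(force_constant) != 1L ||
      !is.finite(force_constant) || force_constant < 0)
    stop("force_constant must be a single non-negative number", call. = FALSE)
  if (length(times) != length(positions))
    stop("times and positions must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a window needs at least 2 samples", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("times must lie on a uniform grid (relative tolerance 1e-9)",
         call. = FALSE)
  structure(list(center = center, force_constant = force_constant,
                 times = as.numeric(times), positions = as.numeric(positions),
                 label = if (is.null(label)) sprintf("z%+.2f", center)
                         else as.character(label)),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "Umbrella window '%s': center %.3f nm, Kf %g kJ/mol/nm^2, %d samples (%.3f-%.3f ns)\n",
    x$label, x$center, x$force_constant, length(x$times),
    x$times[1], x$times[length(x$times)]))
  invisible(x)
}

## samples remaining after discarding the equilibration stretch
window_samples <- function(window, equilibration_time = 0) {
  keep <- window$times > equilibration_time
  window$positions[keep]
}

window_duration <- function(window) {
  window$times[length(window$times)] - window$times[1]
}

window_timestep <- function(window) {
  window$times[2] - window$times[1]
}

#' A set of umbrella-sampling replicates
#'
#' Holds one full umbrella set per replicate.  All replicates must share
#' identical window centers and force constants.  \code{equilibration_time}
#' ns are discarded from the start of every window by downstream analyses.
#'
#' @param replicates list of replicates, each a list of
#'   \code{\link{umbrella_window}} objects in matching order.
#' @param equilibration_time ns discarded from the start of every window;
#'   must be non-negative and shorter than the shortest window.
#' @return an object of class \code{"replicate_set"}.
#' @export
replicate_set <- function(replicates, equilibration_time = 0) {
  if (!is.list(replicates) || length(replicates) < 1L)
    stop("need at least one replicate", call. = FALSE)
  for (rep in replicates) {
    if (!is.list(rep) || !all(vapply(rep, inherits, TRUE, "umbrella_window")))
      stop("each replicate must be a list of umbrella_window objects",
           call. = FALSE)
  }
  ref_centers <- vapply(replicates[[1L]], `[[`, 0, "center")
  ref_kf <- vapply(replicates[[1L]], `[[`, 0, "force_constant")
  for (i in seq_along(replicates)) {
    cen <- vapply(replicates[[i]], `[[`, 0, "center")
    kf <- vapply(replicates[[i]], `[[`, 0, "force_constant")
    if (length(cen) != length(ref_centers) ||
        any(abs(cen - ref_centers) > 1e-9) || any(abs(kf - ref_kf) > 1e-9))
      stop(sprintf(
        "replicate %d does not share the window grid of replicate 1", i),
        call. = FALSE)
  }
  shortest <- min(vapply(unlist(replicates, recursive = FALSE),
                         function(w) w$times[length(w$times)], 0))
  if (equilibration_time < 0 || equilibration_time >= shortest)
    stop("equilibration_time must be >= 0 and shorter than every window",
         call. = FALSE)
  structure(list(replicates = replicates,
                 equilibration_time = equilibration_time,
                 centers = ref_centers, force_constants = ref_kf),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf(
    "Replicate set: %d replicate(s) x %d windows, equilibration discard %.1f ns\n",
    length(x$replicates), length(x$centers), x$equilibration_time))
  invisible(x)
}

n_replicates <- function(reps) length(reps$replicates)

## flatten selected replicates into one window list
pooled_windows <- function(reps, which = seq_along(reps$replicates)) {
  unlist(reps$replicates[which], recursive = FALSE)
}

#' Potential-of-mean-force profile
#'
#' Binned free energy G(z) along the reaction coordinate, anchored so that
#' the bulk-water region averages to zero.  Energies carry an explicit unit
#' tag; internal computation is in kJ/mol.
#'
#' @param bin_centers strictly increasing bin centers (nm).
#' @param free_energy free energies per bin; \code{NA} marks uncovered bins.
#' @param units \code{"kJ/mol"} or \code{"kcal/mol"}.
#' @param reference_frame \code{"bilayer_center"} or \code{"closest_p_layer"}.
#' @param anchor anchoring convention; only \code{"bulk_water_zero"}.
#' @param counts optional per-bin sample counts.
#' @return an object of class \code{"pmf_profile"}.
#' @export
pmf_profile <- function(bin_centers, free_energy,
                        units = c("kJ/mol", "kcal/mol"),
                        reference_frame = c("bilayer_center",
                                            "closest_p_layer"),
                        anchor = "bulk_water_zero", counts = NULL) {
  units <- match.arg(units)
  reference_frame <- match.arg(reference_frame)
  anchor <- match.arg(anchor, "bulk_water_zero")
  if (length(bin_centers) != length(free_energy))
    stop("bin_centers and free_energy must have equal length", call. = FALSE)
  if (any(diff(bin_centers) <= 0))
    stop("bin_centers must be strictly increasing", call. = FALSE)
  structure(list(bin_centers = as.numeric(bin_centers),
                 free_energy = as.numeric(free_energy),
                 units = units, reference_frame = reference_frame,
                 anchor = anchor, counts = counts),
            class = "pmf_profile")
}

#' Convert the energy unit of a PMF profile
#'
#' @param pmf a \code{\link{pmf_profile}}.
#' @param to target unit.
#' @return the converted \code{pmf_profile}.
#' @export
convert_pmf_units <- function(pmf, to = c("kJ/mol", "kcal/mol")) {
  to <- match.arg(to)
  stopifnot(inherits(pmf, "pmf_profile"))
  if (pmf$units == to) return(pmf)
  pmf$free_energy <- convert_energy(pmf$free_energy, pmf$units, to)
  pmf$units <- to
  pmf
}

#' @export
print.pmf_profile <- function(x, ...) {
  rng <- range(x$free_energy, na.rm = TRUE)
  cat(sprintf(
    "PMF profile (%s frame): %d bins over [%.3f, %.3f] nm, G in [%.3f, %.3f] %s, %d uncovered bin(s)\n",
    x$reference_frame, length(x$bin_centers), min(x$bin_centers),
    max(x$bin_centers), rng[1], rng[2], x$units, sum(is.na(x$free_energy))))
  invisible(x)
}

## internal constructor enforcing the D = var/tau bookkeeping
new_diffusion_profile <- function(positions, diffusion, variance, corr_time) {
  ok <- is.finite(diffusion)
  if (!any(ok)) stop("all profile points are masked", call. = FALSE)
  if (any(diffusion[ok] <= 0))
    stop("diffusion coefficients must be positive", call. = FALSE)
  rel <- abs(diffusion[ok] - variance[ok] / corr_time[ok])
  if (any(rel > 1e-9 * abs(diffusion[ok])))
    stop("internal error: D != variance/corr_time", call. = FALSE)
  o <- order(positions)
  structure(list(positions = positions[o], diffusion = diffusion[o],
                 variance = variance[o], corr_time = corr_time[o]),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf(
    "Diffusion profile: %d positions over [%.3f, %.3f] nm, D in [%.4g, %.4g] nm^2/ns\n",
    length(x$positions), min(x$positions), max(x$positions),
    min(x$diffusion, na.rm = TRUE), max(x$diffusion, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.permeability_result <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.null(se) || !is.finite(se)) sprintf("%.4g", v)
    else sprintf("%.4g +/- %.2g", v, se)
  }
  se <- x$standard_errors
  cat("ISDM permeability analysis\n")
  cat(sprintf("  permeability: %s cm/s\n",
              fmt(x$permeability, se[["permeability"]])))
  cat(sprintf("  dG_entry:     %s kcal/mol\n", fmt(x$dg_entry, se[["dg_entry"]])))
  cat(sprintf("  dG_exit:      %s kcal/mol\n", fmt(x$dg_exit, se[["dg_exit"]])))
  invisible(x)
}

#' One coordinate snapshot of a membrane system
#'
#' Probe position plus phosphorus-atom positions of both leaflets in an
#' orthorhombic box whose z axis is the membrane normal.  x/y coordinates
#' are wrapped into the box; z is kept unwrapped because membrane-normal
#' analyses break under z-wrapping.
#'
#' @param probe_xyz numeric length-3 probe position (nm).
#' @param p_atoms_xyz numeric matrix (n x 3) of phosphorus positions (nm),
#'   both leaflets, n >= 4.
#' @param box numeric length-3 box dimensions (nm).
#' @return an object of class \code{"membrane_frame"}.
#' @export
membrane_frame <- function(probe_xyz, p_atoms_xyz, box) {
  probe_xyz <- as.numeric(probe_xyz)
  box <- as.numeric(box)
  stopifnot(length(probe_xyz) == 3L, length(box) == 3L, all(box > 0))
  p_atoms_xyz <- as.matrix(p_atoms_xyz)
  if (ncol(p_atoms_xyz) != 3L || nrow(p_atoms_xyz) < 4L)
    stop("p_atoms_xyz must be an n x 3 matrix with n >= 4", call. = FALSE)
  for (d in 1:2) {  # wrap x/y only
    p_atoms_xyz[, d] <- p_atoms_xyz[, d] %% box[d]
    probe_xyz[d] <- probe_xyz[d] %% box[d]
  }
  structure(list(probe_xyz = probe_xyz, p_atoms_xyz = p_atoms_xyz, box = box),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf(
    "Membrane frame: probe at (%.2f, %.2f, %.2f) nm, %d P atoms, box %.2f x %.2f x %.2f nm\n",
    x$probe_xyz[1], x$probe_xyz[2], x$probe_xyz[3], nrow(x$p_atoms_xyz),
    x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @export
#' @importFrom graphics abline lines
plot.pmf_profile <- function(x, add = FALSE, col = "black", ...) {
  p <- convert_pmf_units(x, "kcal/mol")
  if (add) {
    lines(p$bin_centers, p$free_energy, col = col, ...)
  } else {
    plot(p$bin_centers, p$free_energy, type = "l", col = col,
         xlab = "z (nm)", ylab = "G (kcal/mol)", ...)
    abline(h = 0, lty = 3, col = "grey60")
  }
  invisible(x)
}

#' @export
plot.diffusion_profile <- function(x, ...) {
  plot(x$positions, x$diffusion, type = "b", pch = 16,
       xlab = "z (nm)", ylab = expression(D ~ (nm^2/ns)), ...)
  invisible(x)
}
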
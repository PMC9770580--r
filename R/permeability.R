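#' Position-dependent resistance profile
#'
#' ISDM resistance \eqn{R(z) = \exp(\beta \Delta G(z)) / D(z)} on the PMF
#' bin grid, with \eqn{\Delta G} relative to the bulk-water anchor (the
#' profile's zero) and D linearly interpolated onto the PMF bins
#' (clamped at the profile ends).  Units: with G in kJ/mol and D in
#' nm^2/ns, D is converted to cm^2/s (factor 1e-5) so that integrating
#' R over z in cm yields s/cm.
#'
#' @param pmf a \code{\link{pmf_profile}} with no uncovered interior bins.
#' @param dprof a \code{"diffusion_profile"}.
#' @param thermo a \code{\link{make_thermo}} object.
#' @return an object of class \code{"resistance_profile"}: data frame with
#'   columns \code{position} (nm) and \code{resistance} (s/cm^2).
#' @export
resistance_profile <- function(pmf, dprof, thermo) {
  stopifnot(inherits(pmf, "pmf_profile"),
            inherits(dprof, "diffusion_profile"),
            inherits(thermo, "thermo_params"))
  g <- convert_pmf_units(pmf, "kJ/mol")$free_energy
  if (anyNA(g))
    stop(sprintf(
      "incomplete profile: %d uncovered bin(s) in the PMF; ISDM integration needs a fully covered grid",
      sum(is.na(g))), call. = FALSE)
  d <- approx(dprof$positions, dprof$diffusion, xout = pmf$bin_centers,
              rule = 2, ties = mean)$y
  if (any(!is.finite(d)) || any(d <= 0))
    stop("invalid diffusion: interpolated D must be positive everywhere",
         call. = FALSE)
  r <- exp(thermo$beta * g) / (d * .D_NM2_NS_TO_CM2_S)
  out <- data.frame(position = pmf$bin_centers, resistance = r)
  class(out) <- c("resistance_profile", "data.frame")
  out
}

#' Permeability coefficient from a resistance profile
#'
#' ISDM permeation coefficient
#' \eqn{P = 1 / \int_{z_{lo}}^{z_{hi}} R(z)\,dz} by trapezoidal quadrature,
#' with z converted from nm to cm.
#'
#' @param resistance a \code{\link{resistance_profile}}.
#' @param z_lo,z_hi integration bounds (nm); default the full grid.
#' @return permeability P in cm/s.
#' @export
permeability <- function(resistance, z_lo = NULL, z_hi = NULL) {
  stopifnot(inherits(resistance, "resistance_profile"))
  z <- resistance$position
  if (is.null(z_lo)) z_lo <- min(z)
  if (is.null(z_hi)) z_hi <- max(z)
  if (z_hi - z_lo <= 0)
    stop("invalid range: z_hi must exceed z_lo", call. = FALSE)
  keep <- z >= z_lo - 1e-12 & z <= z_hi + 1e-12
  if (sum(keep) < 2L)
    stop("invalid range: fewer than 2 grid points inside [z_lo, z_hi]",
         call. = FALSE)
  1 / .trapz(z[keep] * .NM_TO_CM, resistance$resistance[keep])
}

#' Mirror a monolayer PMF into a full-bilayer profile
#'
#' A monolayer-referenced PMF covers one leaflet, from the membrane-center
#' end of the grid (lowest z) out to bulk water.  The trans-bilayer profile
#' is built by reflecting about that membrane-center end and dropping the
#' duplicated center point, assuming a symmetric bilayer.
#'
#' @param pmf a \code{\link{pmf_profile}} in the \code{closest_p_layer}
#'   frame whose grid reaches the membrane center at its low-z end.
#' @return a \code{pmf_profile} spanning both leaflets, with attribute
#'   \code{"bilayer_symmetric"} set.
#' @export
mirror_monolayer_profile <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (pmf$reference_frame != "closest_p_layer")
    stop("invalid frame: mirroring requires a closest_p_layer profile",
         call. = FALSE)
  if (isTRUE(attr(pmf, "bilayer_symmetric"))) return(pmf)
  z <- pmf$bin_centers
  g <- pmf$free_energy
  z0 <- z[1L]
  z_new <- c(2 * z0 - rev(z[-1L]), z)
  g_new <- c(rev(g[-1L]), g)
  cnt <- if (!is.null(pmf$counts)) c(rev(pmf$counts[-1L]), pmf$counts)
  out <- pmf_profile(z_new, g_new, units = pmf$units,
                     reference_frame = "closest_p_layer", counts = cnt)
  attr(out, "bilayer_symmetric") <- TRUE
  out
}

## prominence of a local maximum at index i: height above the higher of
## the two deepest minima separating it from the profile ends
.peak_prominence <- function(g, i) {
  left <- if (i > 1L) min(g[1:(i - 1L)]) else g[i]
  right <- if (i < length(g)) min(g[(i + 1L):length(g)]) else g[i]
  g[i] - max(left, right)
}

#' Entry and exit free-energy barriers
#'
#' The entry barrier is the free-energy difference between the interface
#' maximum (the local maximum on the water side of the global minimum,
#' taking the highest such peak, ties broken toward the water side) and
#' bulk water (the anchor, G = 0).  The exit barrier is the difference
#' between that same peak and the global minimum in the membrane center
#' region.  Peaks need a prominence above 0.1 kT to count; with no
#' qualifying interface peak on a profile that decays into the membrane,
#' the bulk plateau itself is the maximum: entry 0, exit the full range.
#'
#' @param pmf an anchored \code{\link{pmf_profile}}; the water side is the
#'   high-z end of the grid.
#' @param thermo a \code{\link{make_thermo}} object (sets the 0.1 kT
#'   prominence threshold).
#' @return a list with \code{dg_entry} and \code{dg_exit} (kcal/mol, both
#'   >= 0) and the peak/minimum positions \code{z_interface}, \code{z_min}
#'   (nm).
#' @export
barriers <- function(pmf, thermo) {
  stopifnot(inherits(pmf, "pmf_profile"), inherits(thermo, "thermo_params"))
  p <- convert_pmf_units(pmf, "kJ/mol")
  g <- p$free_energy
  z <- p$bin_centers
  ok <- !is.na(g)
  g <- g[ok]; z <- z[ok]
  n <- length(g)
  if (n < 3L) stop("profile too short", call. = FALSE)
  if (diff(range(g)) < 0.1 * thermo$kT)
    stop("flat profile: no interface maximum identifiable", call. = FALSE)
  i_min <- which.min(g)
  ## candidate interface peaks: local maxima on the water side of the
  ## global minimum (plateau-tolerant), prominence > 0.1 kT
  side <- seq.int(i_min, n)
  peaks <- integer(0)
  for (i in side) {
    gl <- if (i > 1L) g[i - 1L] else -Inf
    gr <- if (i < n) g[i + 1L] else -Inf
    if (g[i] >= gl && g[i] >= gr && (g[i] > gl || g[i] > gr)) {
      if (.peak_prominence(g, i) > 0.1 * thermo$kT) peaks <- c(peaks, i)
    }
  }
  if (length(peaks)) {
    best <- max(g[peaks])
    i_peak <- max(peaks[g[peaks] >= best - 1e-12])  # tie -> water side
    entry_kj <- max(g[i_peak], 0)
  } else {
    ## profile decays monotonically from the bulk plateau: the anchor end
    ## is the maximum
    i_peak <- n
    entry_kj <- max(g[n], 0)
  }
  exit_kj <- g[i_peak] - g[i_min]
  list(dg_entry = convert_energy(entry_kj, "kJ/mol", "kcal/mol"),
       dg_exit = convert_energy(max(exit_kj, 0), "kJ/mol", "kcal/mol"),
       z_interface = z[i_peak], z_min = z[i_min])
}

#' Full ISDM analysis of a replicate set
#'
#' Runs the whole pipeline on pooled replicate data: WHAM PMF, diffusion
#' profile, optional monolayer-to-bilayer mirroring, resistance profile,
#' permeability coefficient and entry/exit barriers.  Standard errors come
#' from leave-one-out jackknife over replicates, re-running the pooled
#' pipeline on every (n-1)-replicate subset (per-window diffusion
#' coefficients are computed once and subset-averaged).
#'
#' @param reps a \code{\link{replicate_set}}.
#' @param thermo a \code{\link{make_thermo}} object.
#' @param wham_cfg a \code{\link{wham_config}}.
#' @param reference_frame \code{"bilayer_center"} or
#'   \code{"closest_p_layer"}; monolayer profiles are mirrored before
#'   integration.
#' @param max_lag ACF lag cap (ns) passed to the diffusion estimator.
#' @param jackknife compute jackknife errors (needs >= 2 replicates).
#' @return an object of class \code{"permeability_result"}: resistance
#'   profile, \code{permeability} (cm/s), \code{dg_entry}/\code{dg_exit}
#'   (kcal/mol), \code{standard_errors} (named, \code{NA} when
#'   unavailable), jackknife leave-one-out values, and the underlying
#'   \code{pmf} and \code{diffusion} profiles.
#' @export
analyze_system <- function(reps, thermo, wham_cfg,
                           reference_frame = c("bilayer_center",
                                               "closest_p_layer"),
                           max_lag = NULL, jackknife = TRUE) {
  stopifnot(inherits(reps, "replicate_set"))
  reference_frame <- match.arg(reference_frame)
  nrep <- n_replicates(reps)

  ## per-window diffusion, cached per replicate for jackknife reuse
  stage <- "diffusion"
  dprof_for <- function(idx) {
    sub <- replicate_set(reps$replicates[idx], reps$equilibration_time)
    diffusion_profile(sub, thermo, max_lag = max_lag)
  }
  run <- function(idx) {
    stage <<- "WHAM"
    pmf <- solve_wham(pooled_windows(reps, idx), thermo, wham_cfg,
                      reps$equilibration_time, reference_frame)
    stage <<- "diffusion"
    dp <- dprof_for(idx)
    stage <<- "mirroring"
    pmf_full <- if (reference_frame == "closest_p_layer")
      mirror_monolayer_profile(pmf) else pmf
    dp_full <- if (reference_frame == "closest_p_layer") {
      z0 <- pmf$bin_centers[1L]
      new_diffusion_profile(
        c(2 * z0 - rev(dp$positions), dp$positions),
        c(rev(dp$diffusion), dp$diffusion),
        c(rev(dp$variance), dp$variance),
        c(rev(dp$corr_time), dp$corr_time))
    } else dp
    stage <<- "resistance/permeability"
    rp <- resistance_profile(pmf_full, dp_full, thermo)
    P <- permeability(rp)
    stage <<- "barriers"
    b <- barriers(pmf_full, thermo)
    list(pmf = pmf, pmf_full = pmf_full, dprof = dp, resistance = rp,
         values = c(permeability = P, dg_entry = b$dg_entry,
                    dg_exit = b$dg_exit))
  }

  full <- tryCatch(run(seq_len(nrep)), error = function(e)
    stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
         call. = FALSE))

  se <- c(permeability = NA_real_, dg_entry = NA_real_,
          dg_exit = NA_real_)
  loo <- NULL
  if (jackknife && nrep >= 2L) {
    jk <- jackknife_se(nrep, function(idx) run(idx)$values)
    se <- jk$se
    loo <- jk$leave_one_out
  }
  structure(list(resistance_positions = full$resistance$position,
                 resistance = full$resistance$resistance,
                 permeability = unname(full$values["permeability"]),
                 dg_entry = unname(full$values["dg_entry"]),
                 dg_exit = unname(full$values["dg_exit"]),
                 standard_errors = se, leave_one_out = loo,
                 pmf = full$pmf, pmf_full = full$pmf_full,
                 diffusion = full$dprof, n_replicates = nrep),
            class = "permeability_result")
}
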
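#' WHAM configuration
#'
#' Bin grid and convergence settings for the weighted-histogram analysis.
#' The anchor region is the stretch of the reaction coordinate treated as
#' bulk water: the mean free energy over it is shifted to zero.  By default
#' it is the outermost 0.3 nm at the water-side (high-z) end of the grid.
#'
#' @param z_min,z_max grid bounds (nm).
#' @param n_bins number of bins (>= 10, default 200).
#' @param tolerance convergence threshold on max |dF_i| per iteration
#'   (kJ/mol, default 1e-6).
#' @param max_iter iteration cap (default 1e5).
#' @param anchor_region length-2 numeric interval (nm) inside
#'   [z_min, z_max]; \code{NULL} selects \code{c(z_max - 0.3, z_max)}.
#' @return an object of class \code{"wham_config"}.
#' @export
wham_config <- function(z_min, z_max, n_bins = 200L, tolerance = 1e-6,
                        max_iter = 100000L, anchor_region = NULL) {
  stopifnot(is.numeric(z_min), is.numeric(z_max), z_min < z_max)
  if (n_bins < 10L) stop("n_bins must be >= 10", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (is.null(anchor_region)) anchor_region <- c(z_max - 0.3, z_max)
  if (length(anchor_region) != 2L || anchor_region[1] >= anchor_region[2] ||
      anchor_region[1] < z_min - 1e-9 || anchor_region[2] > z_max + 1e-9)
    stop("anchor_region must be an interval inside [z_min, z_max]",
         call. = FALSE)
  structure(list(z_min = z_min, z_max = z_max, n_bins = as.integer(n_bins),
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 anchor_region = anchor_region),
            class = "wham_config")
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Self-consistent iteration of the standard WHAM equations for harmonic
#' biases U_i(z) = 0.5 K_i (z - z_i)^2:
#' \deqn{p(b) = \frac{\sum_i n_i(b)}{\sum_i N_i \exp(\beta(F_i - U_i(z_b)))}, \qquad
#'       e^{-\beta F_i} = \sum_b p(b)\, e^{-\beta U_i(z_b)}\, \Delta z,}
#' iterated until \eqn{\max_i |\Delta F_i|} falls below the tolerance.  The
#' free energy is G(z) = -kT ln p(z), shifted so the mean over the anchor
#' region is zero; bins with zero counts get \code{NA}.
#'
#' @param windows list of \code{\link{umbrella_window}} objects (one
#'   replicate's windows, or several replicates' pooled).
#' @param thermo a \code{\link{make_thermo}} object.
#' @param cfg a \code{\link{wham_config}}.
#' @param equilibration_time ns discarded from the start of every window.
#' @param reference_frame frame tag carried into the profile.
#' @return a \code{\link{pmf_profile}} (kJ/mol) with attributes
#'   \code{"window_offsets"} (converged F_i, kJ/mol), \code{"iterations"}
#'   and \code{"residual"}.
#' @export
solve_wham <- function(windows, thermo, cfg, equilibration_time = 0,
                       reference_frame = c("bilayer_center",
                                           "closest_p_layer")) {
  reference_frame <- match.arg(reference_frame)
  stopifnot(inherits(thermo, "thermo_params"), inherits(cfg, "wham_config"))
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  nw <- length(windows)
  if (!nw) stop("no windows supplied", call. = FALSE)
  edges <- seq(cfg$z_min, cfg$z_max, length.out = cfg$n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  dz <- diff(edges)[1]
  beta <- thermo$beta

  counts <- numeric(cfg$n_bins)
  N <- numeric(nw)
  for (i in seq_len(nw)) {
    s <- window_samples(windows[[i]], equilibration_time)
    s <- s[s >= cfg$z_min & s <= cfg$z_max]
    if (!length(s))
      stop(sprintf(
        "insufficient sampling: window '%s' has no samples in [%.3f, %.3f] after equilibration",
        windows[[i]]$label, cfg$z_min, cfg$z_max), call. = FALSE)
    N[i] <- length(s)
    idx <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- counts + tabulate(idx, nbins = cfg$n_bins)
  }

  ## bias Boltzmann factors, windows x bins; harmless underflow to 0 far out
  B <- matrix(0, nw, cfg$n_bins)
  for (i in seq_len(nw)) {
    w <- windows[[i]]
    B[i, ] <- exp(-beta * 0.5 * w$force_constant * (centers - w$center)^2)
  }

  f <- rep(1, nw)  # f_i = exp(+beta F_i)
  iter <- 0L
  resid <- Inf
  F_old <- numeric(nw)
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(crossprod(B, N * f))
    p <- ifelse(denom > 0, counts / denom, 0)
    Z <- as.numeric(B %*% p) * dz
    F_new <- -thermo$kT * log(Z)
    F_new <- F_new - F_new[1L]
    resid <- max(abs(F_new - F_old))
    f <- exp(beta * F_new)
    F_old <- F_new
    if (resid < cfg$tolerance || iter >= cfg$max_iter) break
  }
  if (resid >= cfg$tolerance && iter >= cfg$max_iter && nw > 1L)
    stop(sprintf(
      "WHAM did not converge in %d iterations (last residual %.3g kJ/mol)",
      cfg$max_iter, resid), call. = FALSE)

  p[counts == 0] <- NA_real_
  p <- p / sum(p * dz, na.rm = TRUE)
  G <- -thermo$kT * log(p)
  in_anchor <- centers >= cfg$anchor_region[1] - 1e-9 &
    centers <= cfg$anchor_region[2] + 1e-9
  g_anchor <- G[in_anchor & !is.na(G)]
  if (!length(g_anchor))
    stop("no covered bins inside the anchor region", call. = FALSE)
  G <- G - mean(g_anchor)

  out <- pmf_profile(centers, G, units = "kJ/mol",
                     reference_frame = reference_frame, counts = counts)
  attr(out, "window_offsets") <- F_old
  attr(out, "iterations") <- iter
  attr(out, "residual") <- resid
  out
}

#' Pooled and per-replicate PMF profiles
#'
#' Runs WHAM once on all replicates' windows jointly (pooled profile) and
#' once per replicate, on an identical bin grid with identical anchoring.
#'
#' @param reps a \code{\link{replicate_set}}.
#' @param thermo a \code{\link{make_thermo}} object.
#' @param cfg a \code{\link{wham_config}}.
#' @param reference_frame frame tag carried into the profiles.
#' @return a list with elements \code{pooled} (a \code{\link{pmf_profile}})
#'   and \code{per_replicate} (list of \code{pmf_profile}s).
#' @export
pooled_and_per_replicate_pmfs <- function(reps, thermo, cfg,
                                          reference_frame = c(
                                            "bilayer_center",
                                            "closest_p_layer")) {
  stopifnot(inherits(reps, "replicate_set"))
  reference_frame <- match.arg(reference_frame)
  eq <- reps$equilibration_time
  pooled <- solve_wham(pooled_windows(reps), thermo, cfg, eq,
                       reference_frame)
  per <- lapply(reps$replicates, solve_wham, thermo = thermo, cfg = cfg,
                equilibration_time = eq, reference_frame = reference_frame)
  list(pooled = pooled, per_replicate = per)
}
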
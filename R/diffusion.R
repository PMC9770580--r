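## FFT-based autocovariance of a centred series, lags 0..max_lag_idx,
## normalised by n (population convention, so lag 0 equals var*(n-1)/n...
## we use the 1/n divisor throughout: C(0) = mean((x - mean(x))^2)).
.acov_fft <- function(x, max_lag_idx) {
  n <- length(x)
  x <- x - mean(x)
  m <- nextn(2L * n)
  fx <- fft(c(x, numeric(m - n)))
  ac <- Re(fft(fx * Conj(fx), inverse = TRUE)) / m
  ac[seq_len(max_lag_idx + 1L)] / n
}

#' Position autocovariance of an umbrella window
#'
#' Autocovariance \eqn{C(t) = \langle \delta z(0)\,\delta z(t)\rangle} of
#' the mean-free reaction coordinate \eqn{\delta z = z - \langle z\rangle},
#' averaged over all valid time origins; \eqn{C(0)} is the (population)
#' variance of z.
#'
#' @param window an \code{\link{umbrella_window}}.
#' @param max_lag largest lag (ns); must be below half the
#'   post-equilibration duration.  Default: one fifth of it.
#' @param equilibration_time ns discarded from the start.
#' @return a data frame with columns \code{lag} (ns) and \code{acov} (nm^2).
#' @export
position_acf <- function(window, max_lag = NULL, equilibration_time = 0) {
  stopifnot(inherits(window, "umbrella_window"))
  x <- window_samples(window, equilibration_time)
  if (length(x) < 100L)
    stop(sprintf(
      "insufficient sampling: window '%s' has %d post-equilibration samples (need >= 100)",
      window$label, length(x)), call. = FALSE)
  dt <- window_timestep(window)
  dur <- (length(x) - 1L) * dt
  if (is.null(max_lag)) max_lag <- dur / 5
  if (max_lag >= dur / 2)
    stop("max_lag must be below half the post-equilibration duration",
         call. = FALSE)
  li <- max(1L, floor(max_lag / dt))
  ac <- .acov_fft(x, li)
  data.frame(lag = dt * (0:li), acov = ac)
}

#' Diffusion coefficient of one umbrella window
#'
#' Local diffusion from the window's position autocorrelation:
#' \eqn{D = \mathrm{var}(z)/\tau} with the correlation time
#' \eqn{\tau = \int_0^\infty C(t)/C(0)\,dt}.  Equivalently
#' \eqn{D = \mathrm{var}(z)^2 / \int_0^\infty C(t)\,dt}.  The integral is
#' evaluated by the trapezoidal rule, truncated at the first non-positive
#' C(t) (method \code{"truncate"}, the default) or taken from a
#' least-squares exponential fit to the positive head of C(t)/C(0)
#' (method \code{"expfit"}).
#'
#' @param window an \code{\link{umbrella_window}}.
#' @param thermo optional \code{\link{make_thermo}} object; when supplied,
#'   the harmonic-sanity ratio var(z)*Kf/kT is attached as attribute
#'   \code{"ou_variance_ratio"} (it tends to 1 for well-sampled harmonic
#'   windows on a locally flat landscape).
#' @param max_lag,equilibration_time passed to \code{\link{position_acf}}.
#' @param method \code{"truncate"} or \code{"expfit"}.
#' @return a list with \code{D} (nm^2/ns), \code{variance} (nm^2),
#'   \code{corr_time} (ns) and \code{position} (nm, the window's mean z).
#' @export
window_diffusion <- function(window, thermo = NULL, max_lag = NULL,
                             equilibration_time = 0,
                             method = c("truncate", "expfit")) {
  method <- match.arg(method)
  ac <- position_acf(window, max_lag, equilibration_time)
  v <- ac$acov[1L]
  if (v <= 0)
    stop(sprintf("window '%s' has zero position variance", window$label),
         call. = FALSE)
  rho <- ac$acov / v
  first_np <- which(rho[-1L] <= 0)[1L]
  if (is.na(first_np))
    stop(sprintf(
      "non-converged ACF: C(t) of window '%s' stays positive over the full lag range; increase max_lag",
      window$label), call. = FALSE)
  if (method == "truncate") {
    ## keep lags 0 .. (first_np-1)*dt (the positive head) and close the
    ## integral with the descent to zero at the truncation point
    k <- first_np
    tau <- .trapz(ac$lag[seq_len(k)], rho[seq_len(k)]) +
      rho[k] * (ac$lag[k + 1L] - ac$lag[k]) / 2
  } else {
    k <- max(first_np, 3L)
    sel <- seq_len(k)[rho[seq_len(k)] > 0]
    fit <- stats::lm(log(rho[sel]) ~ 0 + ac$lag[sel])
    tau <- -1 / unname(stats::coef(fit)[1L])
  }
  if (tau <= 0)
    stop(sprintf("non-positive correlation time for window '%s'",
                 window$label), call. = FALSE)
  x <- window_samples(window, equilibration_time)
  out <- list(D = v / tau, variance = v, corr_time = tau,
              position = mean(x))
  if (!is.null(thermo)) {
    stopifnot(inherits(thermo, "thermo_params"))
    attr(out, "ou_variance_ratio") <-
      v * window$force_constant / thermo$kT
  }
  out
}

#' Position-dependent diffusion profile over a replicate set
#'
#' Computes the per-window diffusion coefficient for every window of every
#' replicate and averages over replicates window by window (replicate
#' membranes differ locally, so ACFs are not pooled).  Positions are the
#' replicate-mean window positions, sorted.  A window that fails (e.g.
#' non-converged ACF) raises a warning and masks the point; a fully masked
#' profile is an error.
#'
#' @param reps a \code{\link{replicate_set}}.
#' @param thermo a \code{\link{make_thermo}} object.
#' @param max_lag largest ACF lag (ns); default one fifth of the
#'   post-equilibration duration.
#' @param method passed to \code{\link{window_diffusion}}.
#' @return a \code{"diffusion_profile"}: positions (nm), diffusion
#'   (nm^2/ns), variance (nm^2) and effective correlation time
#'   variance/D (ns).
#' @export
diffusion_profile <- function(reps, thermo, max_lag = NULL,
                              method = c("truncate", "expfit")) {
  stopifnot(inherits(reps, "replicate_set"))
  method <- match.arg(method)
  nwin <- length(reps$centers)
  nrep <- n_replicates(reps)
  Dm <- Vm <- Pm <- matrix(NA_real_, nrep, nwin)
  for (r in seq_len(nrep)) {
    for (w in seq_len(nwin)) {
      res <- tryCatch(
        window_diffusion(reps$replicates[[r]][[w]], max_lag = max_lag,
                         equilibration_time = reps$equilibration_time,
                         method = method),
        error = function(e) {
          warning(sprintf("replicate %d: %s", r, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (!is.null(res)) {
        Dm[r, w] <- res$D
        Vm[r, w] <- res$variance
        Pm[r, w] <- res$position
      }
    }
  }
  D <- colMeans(Dm, na.rm = TRUE)
  V <- colMeans(Vm, na.rm = TRUE)
  P <- colMeans(Pm, na.rm = TRUE)
  ok <- is.finite(D)
  if (!any(ok)) stop("all windows failed diffusion estimation",
                     call. = FALSE)
  ## corr_time stored as the effective variance/D ratio so that
  ## D = variance/corr_time holds exactly at every point (it equals the
  ## per-window tau when there is a single replicate)
  new_diffusion_profile(P[ok], D[ok], V[ok], V[ok] / D[ok])
}
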
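#' Thickness analysis configuration
#'
#' Cutoffs for local monolayer thickness: phosphorus atoms within
#' \code{local_cutoff} of the probe in the xy plane define the local
#' monolayer plane, while atoms outside \code{center_exclusion} (i.e. those
#' unperturbed by the probe) define the membrane center.  Defaults are
#' 1.0 nm (10 Angstrom) and 1.5 nm (15 Angstrom).
#'
#' @param local_cutoff xy radius (nm) selecting local P atoms.
#' @param center_exclusion xy radius (nm) outside which P atoms are used for
#'   the membrane center; must exceed \code{local_cutoff}.
#' @return an object of class \code{"thickness_config"}.
#' @export
thickness_config <- function(local_cutoff = 1.0, center_exclusion = 1.5) {
  if (!(local_cutoff > 0 && local_cutoff < center_exclusion))
    stop("require 0 < local_cutoff < center_exclusion", call. = FALSE)
  structure(list(local_cutoff = local_cutoff,
                 center_exclusion = center_exclusion),
            class = "thickness_config")
}

## minimum-image xy distance of each P atom to the probe
.xy_min_image_dist <- function(frame) {
  d <- sweep(frame$p_atoms_xyz[, 1:2, drop = FALSE], 2,
             frame$probe_xyz[1:2])
  for (k in 1:2) {
    b <- frame$box[k]
    d[, k] <- d[, k] - b * round(d[, k] / b)
  }
  sqrt(rowSums(d^2))
}

#' Partition phosphorus atoms into leaflets
#'
#' Splits P atoms by the sign of their z coordinate relative to the global
#' mean P z.  Atoms exactly at the mean are assigned to the upper leaflet.
#'
#' @param frame a \code{\link{membrane_frame}}.
#' @return a list with integer index vectors \code{upper} and \code{lower}.
#' @export
assign_leaflets <- function(frame) {
  stopifnot(inherits(frame, "membrane_frame"))
  z <- frame$p_atoms_xyz[, 3]
  mid <- mean(z)
  upper <- which(z >= mid)
  lower <- which(z < mid)
  if (!length(upper) || !length(lower))
    stop("degenerate membrane: all P atoms on one side of the mean plane",
         call. = FALSE)
  list(upper = upper, lower = lower)
}

#' Monolayer-referenced probe coordinate
#'
#' Signed distance (nm) of the probe to the mean z of the closest leaflet's
#' P atoms.  The closest leaflet minimises |z_probe - mean z_leaflet|, ties
#' broken toward the upper leaflet.  The sign is negative when the probe
#' lies between that leaflet's mean plane and the membrane center (deeper
#' insertion), positive on the water side.
#'
#' @param frame a \code{\link{membrane_frame}}.
#' @return a single numeric (nm); attribute \code{"leaflet"} names the
#'   chosen leaflet.
#' @export
monolayer_coordinate <- function(frame) {
  lf <- assign_leaflets(frame)
  z <- frame$p_atoms_xyz[, 3]
  zp <- frame$probe_xyz[3]
  m_up <- mean(z[lf$upper])
  m_lo <- mean(z[lf$lower])
  if (abs(zp - m_up) <= abs(zp - m_lo)) {
    structure(zp - m_up, leaflet = "upper")
  } else {
    structure(m_lo - zp, leaflet = "lower")
  }
}

#' Local monolayer thickness around the probe
#'
#' Half thickness of the probe-side monolayer: the membrane center is the
#' mean z of all P atoms (both leaflets) farther than
#' \code{cfg$center_exclusion} from the probe in the xy plane (minimum
#' image), and the local monolayer plane is the mean z of the probe-side
#' leaflet's P atoms within \code{cfg$local_cutoff}.  The half thickness is
#' the absolute difference of the two.
#'
#' @param frame a \code{\link{membrane_frame}}.
#' @param cfg a \code{\link{thickness_config}}.
#' @return an object of class \code{"thickness_result"}: list with
#'   \code{half_thickness}, \code{membrane_center_z}, \code{n_local},
#'   \code{n_reference} and \code{leaflet}.
#' @export
local_thickness <- function(frame, cfg = thickness_config()) {
  stopifnot(inherits(frame, "membrane_frame"),
            inherits(cfg, "thickness_config"))
  lf <- assign_leaflets(frame)
  side <- attr(monolayer_coordinate(frame), "leaflet")
  side_idx <- lf[[side]]
  d <- .xy_min_image_dist(frame)
  local_idx <- side_idx[d[side_idx] <= cfg$local_cutoff]
  ref_idx <- which(d > cfg$center_exclusion)
  if (!length(local_idx) || !length(ref_idx))
    stop(sprintf(
      "insufficient atoms: %d local P atoms within %.2f nm, %d reference P atoms beyond %.2f nm",
      length(local_idx), cfg$local_cutoff, length(ref_idx),
      cfg$center_exclusion), call. = FALSE)
  z <- frame$p_atoms_xyz[, 3]
  center <- mean(z[ref_idx])
  half <- abs(mean(z[local_idx]) - center)
  structure(list(half_thickness = half, membrane_center_z = center,
                 n_local = length(local_idx), n_reference = length(ref_idx),
                 leaflet = side),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf(
    "Local monolayer thickness (%s leaflet): %.3f nm (center z %.3f nm; %d local / %d reference P atoms)\n",
    x$leaflet, x$half_thickness, x$membrane_center_z, x$n_local,
    x$n_reference))
  invisible(x)
}
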
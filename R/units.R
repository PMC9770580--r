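## Unit conventions used throughout:
##   length nm, time ns, energy kJ/mol (kcal/mol only at reporting),
##   diffusion nm^2/ns, permeability cm/s.

#' Physical constants and unit conversions
#'
#' The gas constant is fixed at \code{R = 0.0083144621} kJ/mol/K; thermal
#' calorie conversion uses 1 kcal = 4.184 kJ.  Diffusion coefficients in
#' nm\eqn{^2}/ns convert to cm\eqn{^2}/s by a factor 1e-5; lengths in nm
#' convert to cm by 1e-7.
#'
#' @name units
#' @keywords internal
NULL

.GAS_CONSTANT_KJ <- 0.0083144621  # kJ mol^-1 K^-1
.KJ_PER_KCAL <- 4.184
.D_NM2_NS_TO_CM2_S <- 1e-5
.NM_TO_CM <- 1e-7

#' Convert energies between kJ/mol and kcal/mol
#'
#' @param x numeric energies.
#' @param from,to one of \code{"kJ/mol"}, \code{"kcal/mol"}.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(4.184, "kJ/mol", "kcal/mol")  # 1
#' @export
convert_energy <- function(x, from = c("kJ/mol", "kcal/mol"),
                           to = c("kJ/mol", "kcal/mol")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "kJ/mol") x / .KJ_PER_KCAL else x * .KJ_PER_KCAL
}

## trapezoidal quadrature on an arbitrary (sorted) grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## local seed scope: run code under a given seed without disturbing the
## caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
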
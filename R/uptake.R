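# Equilibrium SPME extraction: closed-form two-phase mass balance between
# the fiber coating and the aqueous sample.

#' Define an SPME extraction system
#'
#' An equilibrium two-phase system: a polymer-coated fiber of coating
#' volume `vf` immersed in a sample of volume `vs` with initial analyte
#' concentration `c0`, partitioning with coefficient `kfs = Cf/Cs`. Units
#' are the caller's responsibility but must be self-consistent (`vf` and
#' `vs` in the same volume unit; `c0` in mass per that unit).
#'
#' @param kfs Coating-sample partition coefficient (dimensionless, >= 0).
#' @param c0 Initial aqueous concentration (mass/volume, >= 0).
#' @param vf Coating volume (> 0).
#' @param vs Sample volume (> 0).
#' @return A list of class `spme_system`.
#' @examples
#' spme_system(kfs = 566, c0 = 1, vf = 6.6e-4, vs = 1)
#' @export
spme_system <- function(kfs, c0, vf, vs) {
  vals <- c(kfs = kfs, c0 = c0, vf = vf, vs = vs)
  if (!all(is.finite(vals))) stop("all system parameters must be finite",
                                  call. = FALSE)
  if (kfs < 0 || c0 < 0) stop("kfs and c0 must be >= 0", call. = FALSE)
  if (vf <= 0 || vs <= 0) stop("vf and vs must be > 0", call. = FALSE)
  structure(list(kfs = kfs, c0 = c0, vf = vf, vs = vs),
            class = "spme_system")
}

#' Equilibrium mass extracted by the coating
#'
#' Solves the two-phase mass balance `C0 Vs = Cf Vf + Cs Vs` with
#' `Cf = Kfs Cs`: the mass in the coating is
#' `Mf = Kfs C0 Vs Vf / (Kfs Vf + Vs)`. In the negligible-depletion limit
#' (`Vs >> Kfs Vf`) this tends to `Kfs C0 Vf`.
#'
#' @param sys An [spme_system()].
#' @return A list with `mf` (mass in coating), `cf` (coating
#'   concentration), `cs` (residual aqueous concentration).
#' @examples
#' extracted_mass(spme_system(kfs = 100, c0 = 1, vf = 1e-3, vs = 1))
#' @export
extracted_mass <- function(sys) {
  stopifnot(inherits(sys, "spme_system"))
  denom <- sys$kfs * sys$vf + sys$vs
  cs <- sys$c0 * sys$vs / denom
  cf <- sys$kfs * cs
  mf <- cf * sys$vf
  list(mf = mf, cf = cf, cs = cs)
}

#' Fraction of analyte extracted at equilibrium
#'
#' `Mf / (C0 Vs) = Kfs Vf / (Kfs Vf + Vs)`: increasing in the partition
#' coefficient and coating volume, decreasing in sample volume.
#'
#' @param sys An [spme_system()] with `c0 > 0`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' fraction_extracted(spme_system(kfs = 566, c0 = 1, vf = 6.6e-4, vs = 1))
#' @export
fraction_extracted <- function(sys) {
  stopifnot(inherits(sys, "spme_system"))
  if (sys$c0 <= 0) stop("fraction undefined for c0 <= 0", call. = FALSE)
  sys$kfs * sys$vf / (sys$kfs * sys$vf + sys$vs)
}

#' @export
print.spme_system <- function(x, ...) {
  cat(sprintf("<spme_system> Kfs = %g, C0 = %g, Vf = %g, Vs = %g\n",
              x$kfs, x$c0, x$vf, x$vs))
  res <- extracted_mass(x)
  if (x$c0 > 0) {
    cat(sprintf("  equilibrium: Mf = %g (%.2f%% of total analyte)\n",
                res$mf, 100 * fraction_extracted(x)))
  } else {
    cat("  equilibrium: Mf = 0 (no analyte present)\n")
  }
  invisible(x)
}
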
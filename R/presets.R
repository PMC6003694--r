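#' Physical reference-model presets for chromatin
#'
#' A preset bundles the parameters of the fine-scale reference fibre used as
#' the starting point of all coarse-graining calculations: the nuclear
#' volumic density \eqn{\rho} (bp/nm^3), the fine-scale monomer content
#' \eqn{\nu_0} (bp), the bond length \eqn{b_0} (nm), the Kuhn length
#' \eqn{l_{k0}} (nm), the dimensionless entanglement constant \eqn{c}, and a
#' calibrated entanglement size \eqn{N_{e0}} (bp).
#'
#' The built-in presets use the nucleosomal-scale fibre
#' (\eqn{\nu_0 = 200} bp, \eqn{b_0 = 10.6} nm, \eqn{l_{k0} = 55.4} nm) at the
#' typical densities of haploid budding yeast (0.005 bp/nm^3), drosophila
#' late embryos (0.009) and mammalian nuclei (0.015), with calibrated
#' entanglement sizes of 920, 285 and 102 kbp respectively.  The calibrated
#' value takes precedence over the phenomenological entanglement-length
#' relation, whose absolute normalisation is uncertain to a factor of order
#' one; the relation is still used for the density scaling (see
#' [entanglement()]).
#'
#' @param species one of `"yeast"`, `"drosophila"`, `"mammal"`, or
#'   `"custom"` (in which case all numeric arguments must be supplied).
#' @param rho volumic density, bp/nm^3.
#' @param nu0 bp per fine-scale monomer.
#' @param b0 fine-scale bond length, nm.
#' @param lk0 fine-scale Kuhn length, nm.
#' @param c_ent dimensionless entanglement constant (default 19).
#' @param Ne0 calibrated entanglement size in bp, or `NA` to derive it from
#'   the entanglement-length relation (with a warning downstream).
#' @return an object of class `chromatin_preset`.
#' @examples
#' chromatin_preset("drosophila")
#' chromatin_preset("custom", rho = 0.007, nu0 = 200, b0 = 10.6, lk0 = 55.4)
#' @export
chromatin_preset <- function(species = c("drosophila", "yeast", "mammal", "custom"),
                             rho = NULL, nu0 = 200, b0 = 10.6, lk0 = 55.4,
                             c_ent = 19, Ne0 = NULL) {
  species <- match.arg(species)
  builtin <- list(
    yeast      = list(rho = 0.005, Ne0 = 920e3),
    drosophila = list(rho = 0.009, Ne0 = 285e3),
    mammal     = list(rho = 0.015, Ne0 = 102e3)
  )
  if (species != "custom") {
    if (is.null(rho)) rho <- builtin[[species]]$rho
    if (is.null(Ne0)) Ne0 <- builtin[[species]]$Ne0
  } else {
    if (is.null(rho)) stop("custom preset requires `rho`")
    if (is.null(Ne0)) Ne0 <- NA_real_
  }
  stopifnot(rho > 0, nu0 > 0, b0 > 0, lk0 >= b0, c_ent > 0)
  if (!is.na(Ne0) && Ne0 <= 0) stop("Ne0 must be positive when supplied")
  structure(
    list(species = species, rho = rho, nu0 = nu0, b0 = b0, lk0 = lk0,
         c_ent = c_ent, Ne0 = Ne0),
    class = "chromatin_preset"
  )
}

#' @export
print.chromatin_preset <- function(x, ...) {
  cat("<chromatin_preset> ", x$species, "\n", sep = "")
  cat(sprintf("  rho  = %.4g bp/nm^3   nu0 = %g bp\n", x$rho, x$nu0))
  cat(sprintf("  b0   = %.4g nm        lk0 = %.4g nm   (lk0/b0 = %.3g)\n",
              x$b0, x$lk0, x$lk0 / x$b0))
  cat(sprintf("  c    = %.3g           Ne0 = %s\n", x$c_ent,
              if (is.na(x$Ne0)) "uncalibrated (Eq.-1 fallback)"
              else sprintf("%.4g kbp (calibrated)", x$Ne0 / 1e3)))
  invisible(x)
}

#' Nuclear volumic density of chromatin
#'
#' The volumic density \eqn{\rho} is the genome size divided by the average
#' nuclear volume.  Either the volume (nm^3) or a spherical-equivalent
#' diameter (nm) may be given.
#'
#' @param genome_size genome size in bp.
#' @param nuclear_volume nuclear volume in nm^3.
#' @param nuclear_diameter nuclear diameter in nm (sphere assumed).
#' @return density in bp/nm^3.
#' @examples
#' nuclear_density(6e9, nuclear_diameter = 9000)      # ~0.015 (human)
#' nuclear_density(12.2e6, nuclear_volume = 2.6e9)    # ~0.005 (yeast)
#' @export
nuclear_density <- function(genome_size, nuclear_volume = NULL,
                            nuclear_diameter = NULL) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (is.null(nuclear_volume) == is.null(nuclear_diameter))
    stop("give exactly one of `nuclear_volume` or `nuclear_diameter`")
  if (!is.null(nuclear_diameter)) {
    if (nuclear_diameter <= 0) stop("nuclear_diameter must be positive")
    nuclear_volume <- (4 / 3) * pi * (nuclear_diameter / 2)^3
  }
  if (nuclear_volume <= 0) stop("nuclear_volume must be positive")
  genome_size / nuclear_volume
}

#' Entanglement length and entanglement ratio
#'
#' Computes the Kuhn-segment density \eqn{\rho_k = (\rho/\nu_0)(b_0/l_{k0})},
#' the entanglement length \eqn{L_e = l_{k0} (c / (\rho_k l_{k0}^3))^2}, the
#' entanglement size \eqn{N_e = \nu_0 L_e / b_0} (bp), and the entanglement
#' ratio \eqn{L/L_e} for a chain of given genomic length.
#'
#' When the preset carries a calibrated \code{Ne0}, the reported \eqn{N_e}
#' equals \code{Ne0} at the preset's own density and scales as
#' \eqn{\rho^{-2}} away from it (the density dependence of the
#' entanglement-length relation at fixed fibre parameters); \code{rho} may be
#' used to query a different density with the same fibre.  Uncalibrated
#' presets fall back to the absolute relation, with a warning, since its
#' normalisation is uncertain.
#'
#' @param preset a [chromatin_preset()].
#' @param chain_length chain length in bp.
#' @param rho optional density override, bp/nm^3 (defaults to the preset's).
#' @return a list of class `entanglement_report` with fields `Le` (nm),
#'   `Ne` (bp), `rho_k` (nm^-3), `ratio` (dimensionless `chain_length/Ne`).
#' @examples
#' ent <- entanglement(chromatin_preset("drosophila"), chain_length = 20e6)
#' ent$ratio   # ~70
#' @export
entanglement <- function(preset, chain_length, rho = NULL) {
  stopifnot(inherits(preset, "chromatin_preset"), chain_length > 0)
  if (is.null(rho)) rho <- preset$rho
  if (rho <= 0) stop("rho must be positive")
  rho_k <- (rho / preset$nu0) * (preset$b0 / preset$lk0)
  if (rho_k * preset$lk0^3 == 0) stop("degenerate Kuhn-segment density")
  Le_raw <- preset$lk0 * (preset$c_ent / (rho_k * preset$lk0^3))^2
  Ne_raw <- preset$nu0 * Le_raw / preset$b0
  if (!is.na(preset$Ne0)) {
    # calibrated: anchor Ne at the preset density, keep the rho^-2 scaling
    Ne <- preset$Ne0 * (preset$rho / rho)^2
    Le <- Ne * preset$b0 / preset$nu0
  } else {
    warning("preset has no calibrated Ne0; using the absolute ",
            "entanglement-length relation, whose normalisation is ",
            "uncertain to a factor of order one")
    Ne <- Ne_raw
    Le <- Le_raw
  }
  structure(list(Le = Le, Ne = Ne, rho_k = rho_k,
                 ratio = chain_length / Ne),
            class = "entanglement_report")
}

#' @export
print.entanglement_report <- function(x, ...) {
  cat("<entanglement_report>\n")
  cat(sprintf("  Le    = %.4g nm     Ne = %.4g kbp\n", x$Le, x$Ne / 1e3))
  cat(sprintf("  rho_k = %.4g nm^-3  L/Le = %.4g\n", x$rho_k, x$ratio))
  invisible(x)
}
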
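#' Volume-fraction penalty of naive coarse-graining
#'
#' For a coarse-graining that neglects bending rigidity and sets the new bond
#' length to the root-mean-square end-to-end distance of the underlying
#' subchain, the lattice volume fraction grows as
#' \deqn{\Phi/\Phi_0 = n^{1/2} (l_{k0}/b_0)^{3/2},}
#' which quickly exceeds 1 for dense fibres — the motivation for the
#' rigidity-controlled strategy of [solve_cg_geometry()].
#'
#' @param n coarse-graining factor (fine monomers per CG monomer), >= 1.
#' @param stiffness_ratio fine-scale `lk0/b0`, >= 1.
#' @return the ratio `Phi/Phi0`.
#' @examples
#' naive_cg_phi_ratio(5, 5)   # 25: already unsimulable at 1 kbp resolution
#' @export
naive_cg_phi_ratio <- function(n, stiffness_ratio) {
  stopifnot(n >= 1, stiffness_ratio >= 1)
  sqrt(n) * stiffness_ratio^1.5
}

# fcc volume per site: cubic cell of edge b*sqrt(2) holds 4 sites
.fcc_site_volume <- function(b) b^3 / sqrt(2)

# maximum lk/b reachable on the fcc stored-length chain: (1 + 12/13)/(1 - 12/13)
.LK_B_CAP <- 25

#' Entanglement-conserving coarse-grained lattice geometry
#'
#' Given a fine-scale preset, a coarse-graining factor \eqn{n} and a target
#' lattice volume fraction \eqn{\Phi}, returns the bond length and Kuhn
#' length of the coarse-grained lattice chain that conserve simultaneously
#' the volumic density and the entanglement ratio \eqn{L/L_e}:
#' \deqn{b = (\sqrt{2}\, n \Phi / \rho_{FS})^{1/3}, \qquad
#'       l_k/b = [(b_0/L_{e0})\, n c^2 / \Phi^2]^{1/3},}
#' with \eqn{\rho_{FS} = \rho/\nu_0} the density in fine-scale monomers and
#' \eqn{L_{e0} = N_{e0} b_0 / \nu_0} the calibrated entanglement length.  The
#' \eqn{\sqrt 2} comes from the fcc per-site volume \eqn{b^3/\sqrt 2}.
#'
#' The resulting stiffness must stay below the lattice cap
#' \eqn{l_k/b < 25}, the infinite-rigidity limit of the stored-length chain.
#'
#' @param preset a calibrated [chromatin_preset()].
#' @param n coarse-graining factor, >= 1.
#' @param phi target lattice volume fraction, in (0, 2].
#' @return list with `b` (nm), `lk` (nm), `lk_b` (ratio), `phi0`
#'   (fine-scale volume fraction `rho_FS * b0^3 / sqrt(2)`, reported for
#'   reference).
#' @examples
#' solve_cg_geometry(chromatin_preset("drosophila"), n = 50, phi = 0.97)
#' @export
solve_cg_geometry <- function(preset, n, phi) {
  stopifnot(inherits(preset, "chromatin_preset"), n >= 1, phi > 0, phi <= 2)
  if (is.na(preset$Ne0))
    stop("solve_cg_geometry requires a preset with calibrated Ne0")
  rho_fs <- preset$rho / preset$nu0
  Le0 <- preset$Ne0 * preset$b0 / preset$nu0
  b <- (sqrt(2) * n * phi / rho_fs)^(1 / 3)
  lk_b <- ((preset$b0 / Le0) * n * preset$c_ent^2 / phi^2)^(1 / 3)
  if (lk_b >= .LK_B_CAP)
    stop(sprintf(
      "unreachable rigidity: lk/b = %.3g >= %d, the fcc stored-length cap; ",
      lk_b, .LK_B_CAP), "increase phi or decrease n")
  if (lk_b < 1) lk_b <- 1   # lattice chain cannot be softer than kappa = 0
  list(b = b, lk = lk_b * b, lk_b = lk_b,
       phi0 = rho_fs * preset$b0^3 / sqrt(2))
}

#' Boltzmann mean bond-angle cosine on the fcc lattice
#'
#' For a bending energy \eqn{E(\theta) = \kappa (1 - \cos\theta)} per bond
#' angle, the 12 fcc bond directions relative to a fixed previous bond have
#' \eqn{\cos\theta \in \{1, 1/2, 0, -1/2, -1\}} with multiplicities
#' \eqn{\{1, 4, 2, 4, 1\}}.  The Boltzmann average has the closed form
#' \deqn{\langle\cos\theta\rangle =
#'   \frac{1 + 2 e^{-\kappa/2} - 2 e^{-3\kappa/2} - e^{-2\kappa}}
#'        {1 + 4 e^{-\kappa/2} + 2 e^{-\kappa} + 4 e^{-3\kappa/2} + e^{-2\kappa}}.}
#'
#' @param kappa bending rigidity in units of kT, >= 0. Vectorised.
#' @return the mean cosine, in [0, 1).
#' @export
mean_cos_theta <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  e1 <- exp(-kappa / 2)
  e2 <- exp(-kappa)
  e3 <- exp(-1.5 * kappa)
  e4 <- exp(-2 * kappa)
  (1 + 2 * e1 - 2 * e3 - e4) / (1 + 4 * e1 + 2 * e2 + 4 * e3 + e4)
}

#' Kuhn-length ratio of the stored-length fcc chain
#'
#' The stored-length chain has 13 bond states (12 lattice directions plus the
#' zero-length bond), giving a bond-direction correlation
#' \eqn{x = (12/13)\langle\cos\theta\rangle} and the Kuhn ratio
#' \eqn{l_k/b = (1 + x)/(1 - x)}, which increases from 1 at \eqn{\kappa = 0}
#' to the cap 25 as \eqn{\kappa \to \infty}.
#'
#' @param kappa bending rigidity in kT, >= 0. Vectorised.
#' @return `lk/b`, in [1, 25).
#' @seealso [kappa_from_kuhn_ratio()] for the numerical inverse.
#' @export
kuhn_ratio_from_kappa <- function(kappa) {
  x <- (12 / 13) * mean_cos_theta(kappa)
  (1 + x) / (1 - x)
}

#' Bending rigidity from a target Kuhn-length ratio
#'
#' Numerical inverse of [kuhn_ratio_from_kappa()] by root bracketing on the
#' strictly monotone map; tolerance 1e-10 in the target ratio.
#'
#' @param target desired `lk/b`, in [1, 25).
#' @return `kappa` in kT.
#' @export
kappa_from_kuhn_ratio <- function(target) {
  if (length(target) > 1)
    return(vapply(target, kappa_from_kuhn_ratio, numeric(1)))
  if (target < 1 || target >= .LK_B_CAP)
    stop(sprintf("unreachable rigidity: lk/b must lie in [1, %d), got %.4g",
                 .LK_B_CAP, target))
  if (target == 1) return(0)
  # kuhn_ratio(kappa) - target is monotone; bracket kappa generously
  hi <- 1
  while (kuhn_ratio_from_kappa(hi) < target) hi <- hi * 2
  stats::uniroot(function(k) kuhn_ratio_from_kappa(k) - target,
                 lower = 0, upper = hi, tol = 1e-12)$root
}

#' Mean squared end-to-end distance of the phantom stored-length chain
#'
#' For a phantom (non-interacting) stored-length fcc chain of `N` beads with
#' bond-direction correlation \eqn{x},
#' \deqn{\langle R_e^2\rangle = \frac{12}{13} b^2 \left[
#'   (N-1)\frac{1+x}{1-x} - \frac{2x(1 - x^{N-1})}{(1-x)^2} \right].}
#' The prefactor 12/13 is the probability that a bond has non-zero length.
#'
#' @param N number of beads, >= 1.
#' @param kappa bending rigidity, kT.
#' @param b bond length, nm.
#' @return mean squared end-to-end distance, nm^2.
#' @export
phantom_end_to_end <- function(N, kappa, b = 1) {
  stopifnot(N >= 1)
  if (N == 1) return(0)
  x <- (12 / 13) * mean_cos_theta(kappa)
  if (x < 1e-12) {
    # freely-jointed limit with stored length; avoids 0 * 1/0^2 noise
    return((12 / 13) * b^2 * (N - 1))
  }
  (12 / 13) * b^2 *
    ((N - 1) * (1 + x) / (1 - x) - 2 * x * (1 - x^(N - 1)) / (1 - x)^2)
}

#' Table of coarse-graining parameters
#'
#' For each requested coarse-graining resolution, solves the
#' entanglement-conserving geometry and reports the full parameter record:
#' resolution \eqn{\nu} (bp), volume fraction \eqn{\Phi}, Kuhn size
#' \eqn{N_k = \nu l_k / b} (bp), bond length \eqn{b} (nm), Kuhn length
#' \eqn{l_k} (nm) and bending rigidity \eqn{\kappa} (kT).  Each row may be
#' specified either by a target \eqn{\Phi} or by a target Kuhn size
#' \eqn{N_k}, in which case the \eqn{\Phi \leftrightarrow N_k} relation is
#' inverted numerically.
#'
#' @param preset a calibrated [chromatin_preset()].
#' @param nu vector of coarse-graining resolutions, bp per monomer.
#' @param phi vector of target volume fractions (same length as `nu`), or
#'   `NULL` if `Nk` is given.
#' @param Nk vector of target Kuhn sizes in bp, or `NULL` if `phi` is given.
#' @return a data.frame with columns `nu`, `n`, `phi`, `Nk`, `b`, `lk`,
#'   `kappa`, `sec_per_mcs` (NA until filled by [time_map()]).
#' @examples
#' build_cg_table(chromatin_preset("drosophila"),
#'                nu = c(2000, 10000), phi = c(0.049, 0.97))
#' @export
build_cg_table <- function(preset, nu, phi = NULL, Nk = NULL) {
  stopifnot(inherits(preset, "chromatin_preset"))
  if (is.null(phi) == is.null(Nk))
    stop("give exactly one of `phi` or `Nk`")
  if (!is.null(Nk)) {
    stopifnot(length(Nk) == length(nu))
    phi <- mapply(function(nu_i, nk_i) phi_from_kuhn_size(preset, nu_i, nk_i),
                  nu, Nk)
  }
  stopifnot(length(phi) == length(nu))
  rows <- mapply(function(nu_i, phi_i) {
    n <- nu_i / preset$nu0
    if (abs(n - round(n)) > 1e-9)
      stop("nu must be an integer multiple of the preset's nu0")
    g <- solve_cg_geometry(preset, n, phi_i)
    data.frame(nu = nu_i, n = round(n), phi = phi_i,
               Nk = nu_i * g$lk_b, b = g$b, lk = g$lk,
               kappa = kappa_from_kuhn_ratio(g$lk_b),
               sec_per_mcs = NA_real_)
  }, nu, phi, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Volume fraction that realises a target Kuhn size
#'
#' Inverts \eqn{N_k(\Phi) = \nu\, [(b_0/L_{e0}) n c^2 / \Phi^2]^{1/3}} for
#' \eqn{\Phi} at fixed resolution: \eqn{\Phi = [ (b_0/L_{e0}) n c^2
#' (\nu/N_k)^3 ]^{1/2}}.
#'
#' @param preset a calibrated [chromatin_preset()].
#' @param nu resolution, bp per monomer.
#' @param Nk target Kuhn size, bp.
#' @return the lattice volume fraction `phi`.
#' @export
phi_from_kuhn_size <- function(preset, nu, Nk) {
  stopifnot(inherits(preset, "chromatin_preset"), Nk >= nu)
  n <- nu / preset$nu0
  Le0 <- preset$Ne0 * preset$b0 / preset$nu0
  phi <- sqrt((preset$b0 / Le0) * n * preset$c_ent^2 * (nu / Nk)^3)
  if (phi > 2)
    stop(sprintf("infeasible volume fraction %.3g > 2 for Nk = %g", phi, Nk))
  phi
}
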
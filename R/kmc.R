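#' Energy model: bending rigidity plus epigenomic copolymer interactions
#'
#' The Hamiltonian is a bending term \eqn{\kappa(1 - \cos\theta)} per angle
#' between two consecutive non-zero bonds, plus a state-pair term
#' \eqn{U_{e(i), e(j)}} for every unordered monomer pair \eqn{|i - j| \ge 2}
#' occupying nearest-neighbour lattice sites.  The block-copolymer case used
#' for chromatin has \eqn{U_{e,e} = E_i} on the diagonal (same-state
#' attraction when \eqn{E_i < 0}) and zero off-diagonal.
#'
#' Zero-length (stored-length) bonds carry no bending energy and break the
#' angle chain; permanently bonded pairs (\eqn{|i - j| = 1}) are excluded
#' from the interaction sum unless `include_bonded_pairs` is set.
#'
#' @param kappa bending rigidity, kT (>= 0 for physical presets).
#' @param U symmetric state-pair interaction matrix in kT (row/column names
#'   give the state alphabet), or `NULL` for none.
#' @param E_i convenience: builds a diagonal `U` with `E_i` on the diagonal
#'   for the given `states` alphabet.
#' @param states state alphabet used with `E_i`.
#' @param include_bonded_pairs count `|i-j| = 1` nearest-neighbour-site
#'   pairs in the interaction sum (default FALSE).
#' @return an object of class `energy_model`.
#' @examples
#' energy_model(kappa = 2)
#' energy_model(kappa = 1.5, E_i = -0.1)
#' @export
energy_model <- function(kappa = 0, U = NULL, E_i = NULL,
                         states = c("active", "HP1", "PcG", "black"),
                         include_bonded_pairs = FALSE) {
  stopifnot(is.numeric(kappa), length(kappa) == 1)
  if (!is.null(E_i)) {
    if (!is.null(U)) stop("give either `U` or `E_i`, not both")
    U <- diag(E_i, length(states))
    dimnames(U) <- list(states, states)
  }
  if (is.null(U)) {
    U <- matrix(0, 0, 0)
  } else {
    stopifnot(is.matrix(U), nrow(U) == ncol(U),
              isTRUE(all.equal(U, t(U))))
    if (is.null(rownames(U))) dimnames(U) <- list(states, states)
  }
  structure(list(kappa = kappa, U = U,
                 include_bonded_pairs = include_bonded_pairs),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> kappa = %.4g kT", x$kappa))
  if (length(x$U)) {
    cat(sprintf(", %d states, diag(U) = [%s] kT",
                nrow(x$U), paste(signif(diag(x$U), 3), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# map conformation states to 1-based integers in the model's alphabet
.state_codes <- function(conf, model) {
  if (is.null(conf$states) || length(model$U) == 0) return(integer(0))
  alphabet <- rownames(model$U)
  codes <- match(as.character(conf$states), alphabet)
  if (anyNA(codes))
    stop("conformation has states outside the model's alphabet: ",
         paste(unique(conf$states[is.na(codes)]), collapse = ", "))
  as.integer(codes)
}

#' Total energy of a conformation
#'
#' @param conf a [conformation()] (with states set if the model has a
#'   non-zero interaction matrix).
#' @param model an [energy_model()].
#' @return total energy in kT.
#' @export
total_energy <- function(conf, model) {
  codes <- .state_codes(conf, model)
  if (length(model$U) > 0 && any(diag(model$U) != 0) && is.null(conf$states))
    stop("non-zero U requires per-monomer states")
  cpp_total_energy(conf$pos, conf$img, conf$lattice$twoS, model$kappa,
                   codes, if (length(model$U)) model$U else matrix(0, 0, 0),
                   model$include_bonded_pairs)
}

#' One trial Monte Carlo move
#'
#' Draws (or accepts as arguments) a monomer and one of the 12 lattice
#' directions, applies the geometric legality rules (occupancy and
#' connectivity) and the Metropolis criterion, and returns the outcome with
#' the updated conformation.  Mostly useful for tests and demonstrations;
#' production dynamics run through [kmc_run()].
#'
#' @param conf a [conformation()].
#' @param model an [energy_model()].
#' @param monomer 1-based monomer index, or `NULL` to draw uniformly.
#' @param direction 1-based direction index (1..12), or `NULL` to draw.
#' @return list with `accepted`, `legal`, `dE` and the (possibly updated)
#'   `conformation`.
#' @export
kmc_attempt_move <- function(conf, model, monomer = NULL, direction = NULL) {
  codes <- .state_codes(conf, model)
  res <- cpp_attempt_move(conf$pos, conf$img, conf$lattice$twoS, model$kappa,
                          codes, if (length(model$U)) model$U else matrix(0, 0, 0),
                          model$include_bonded_pairs,
                          if (is.null(monomer)) -1L else as.integer(monomer),
                          if (is.null(direction)) -1L else as.integer(direction))
  out_conf <- conformation(res$pos, conf$lattice, img = res$img,
                           states = conf$states, seed = conf$seed)
  list(accepted = res$accepted, legal = res$legal, dE = res$dE,
       conformation = out_conf)
}

#' KMC run configuration
#'
#' @param n_mcs number of Monte Carlo steps; one MCS is `N` trial moves.
#' @param snapshot_every recording cadence in MCS (default 1000).
#' @param seed RNG seed for the run.
#' @param energy_check_every cadence (MCS) of the full-energy audit that
#'   cross-checks the incrementally tracked energy (0 disables).
#' @return list of class `kmc_config`.
#' @export
kmc_config <- function(n_mcs, snapshot_every = 1000L, seed = 1L,
                       energy_check_every = 0L) {
  stopifnot(n_mcs >= 0, snapshot_every >= 1, energy_check_every >= 0)
  structure(list(n_mcs = n_mcs, snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed),
                 energy_check_every = as.integer(energy_check_every)),
            class = "kmc_config")
}

#' Run kinetic Monte Carlo dynamics
#'
#' One Monte Carlo step (MCS) consists of `N` trial moves: a monomer chosen
#' uniformly is displaced to one of its 12 nearest-neighbour sites chosen
#' uniformly; the move is accepted with probability
#' \eqn{\min(1, e^{-\Delta E/kT})} provided chain connectivity and the
#' stored-length occupancy rule are maintained.  Snapshots of the unfolded
#' coordinates are recorded every `snapshot_every` MCS (the initial state is
#' snapshot 0).  Runs are deterministic given the seed.
#'
#' @param conf initial [conformation()].
#' @param model an [energy_model()].
#' @param config a [kmc_config()].
#' @return an object of class `chrom_trajectory`: list with `coords`
#'   (integer array N x 3 x n_snapshots of unwrapped grid coordinates),
#'   `mcs`, `energy`, `acceptance_rate`, `lattice`, `states`, `model`,
#'   `config`, `audit_max_error`.
#' @export
kmc_run <- function(conf, model, config) {
  stopifnot(inherits(conf, "chrom_conformation"),
            inherits(model, "energy_model"),
            inherits(config, "kmc_config"))
  bad <- validate_conformation(conf)
  if (length(bad))
    stop("invalid initial conformation: ", paste(utils::head(bad, 3),
         collapse = "; "))
  codes <- .state_codes(conf, model)
  res <- cpp_kmc_run(conf$pos, conf$img, conf$lattice$twoS, model$kappa,
                     codes, if (length(model$U)) model$U else matrix(0, 0, 0),
                     model$include_bonded_pairs, config$n_mcs,
                     config$snapshot_every, config$energy_check_every,
                     as.double(config$seed))
  N <- nrow(conf$pos)
  nsnap <- as.integer(res$n_snapshots)
  coords <- array(res$snapshots, dim = c(N, 3, nsnap))
  structure(list(coords = coords, mcs = res$mcs, energy = res$energy,
                 acceptance_rate = res$acceptance_rate,
                 audit_max_error = res$audit_max_error,
                 lattice = conf$lattice, states = conf$states,
                 model = model, config = config),
            class = "chrom_trajectory")
}

#' @export
print.chrom_trajectory <- function(x, ...) {
  cat(sprintf(
    "<chrom_trajectory> N = %d, %d snapshots over %g MCS (every %d)\n",
    dim(x$coords)[1], dim(x$coords)[3], max(x$mcs), x$config$snapshot_every))
  cat(sprintf("  acceptance = %.3f, seed = %d\n",
              x$acceptance_rate, x$config$seed))
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj a `chrom_trajectory`.
#' @return integer.
#' @export
n_snapshots <- function(traj) dim(traj$coords)[3]

#' Extract one snapshot as a conformation
#'
#' @param traj a `chrom_trajectory`.
#' @param k snapshot index (1-based).
#' @return a [conformation()].
#' @export
snapshot_conformation <- function(traj, k) {
  stopifnot(k >= 1, k <= n_snapshots(traj))
  refold(traj$coords[, , k], traj$lattice, states = traj$states)
}

#' Unfolded snapshot coordinates in nm
#'
#' @param traj a `chrom_trajectory`.
#' @return numeric array N x 3 x n_snapshots, nm.
#' @export
traj_coords_nm <- function(traj) traj$coords * traj$lattice$a

#' Run independent replicas
#'
#' Replica `k` uses seed `base_seed + k - 1` both for its initial
#' conformation (via `conf_generator(seed)`) and for its dynamics; results
#' are order-stable.
#'
#' @param conf_generator function(seed) returning an initial
#'   [conformation()].
#' @param model an [energy_model()].
#' @param config a [kmc_config()]; its seed is the base seed.
#' @param n_replicas number of replicas, >= 1.
#' @return list of `chrom_trajectory`.
#' @export
run_replicas <- function(conf_generator, model, config, n_replicas) {
  stopifnot(n_replicas >= 1)
  lapply(seq_len(n_replicas), function(k) {
    seed_k <- config$seed + k - 1L
    conf <- conf_generator(seed_k)
    cfg <- config
    cfg$seed <- as.integer(seed_k)
    kmc_run(conf, model, cfg)
  })
}
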
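# Config-driven workflows: resolve a structured YAML config into a fully
# derived run manifest, then wire initialisation, simulation and analysis.

.known_keys <- list(
  preset = c("species", "rho", "nu0", "b0", "lk0", "c", "ne0"),
  cg = c("nu", "phi", "nk"),
  model = c("kappa", "e_i", "include_bonded_pairs"),
  run = c("n_monomers", "region_bp", "n_mcs", "snapshot_every",
          "n_replicas", "seed", "init", "energy_check_every"),
  io = c("outdir", "prefix"))

# small stable content hash (polynomial rolling hash over the serialized
# object, kept within double-exact integer range)
.manifest_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Resolve a run configuration into a derived manifest
#'
#' Reads a YAML config with sections `preset`, `cg`, `model`, `run`, `io`,
#' validates the schema (unknown keys are rejected), and computes every
#' derived quantity: coarse-graining factor `n`, box size `S` and realised
#' volume fraction, bond length `b`, Kuhn length `lk`, bending rigidity
#' `kappa`, Kuhn size `Nk`, and the default contact thresholds.  The
#' realised (not the requested) volume fraction is fed into the geometry
#' solver so theory and lattice agree.
#'
#' @param file path to a YAML config, or an equivalent named list.
#' @return list of class `run_config` with the original sections plus a
#'   `derived` section and a `manifest_hash`.
#' @export
resolve_config <- function(file) {
  cfg <- if (is.character(file)) yaml::read_yaml(file) else file
  bad_sections <- setdiff(names(cfg), names(.known_keys))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (sec in names(.known_keys)) {
    extra <- setdiff(names(cfg[[sec]]), .known_keys[[sec]])
    if (length(extra))
      stop("unknown key(s) in [", sec, "]: ", paste(extra, collapse = ", "))
  }
  p <- cfg$preset
  preset <- chromatin_preset(
    species = if (is.null(p$species)) "custom" else p$species,
    rho = p$rho,
    nu0 = if (is.null(p$nu0)) 200 else p$nu0,
    b0 = if (is.null(p$b0)) 10.6 else p$b0,
    lk0 = if (is.null(p$lk0)) 55.4 else p$lk0,
    c_ent = if (is.null(p$c)) 19 else p$c,
    Ne0 = p$ne0)
  cg <- cfg$cg
  if (is.null(cg$nu)) stop("cg section requires `nu`")
  if (is.null(cg$phi) == is.null(cg$nk))
    stop("cg section requires exactly one of `phi` or `nk`")
  phi_target <- if (!is.null(cg$phi)) cg$phi
                else phi_from_kuhn_size(preset, cg$nu, cg$nk)
  if (phi_target > 2)
    stop(sprintf("infeasible volume fraction %.3g > 2", phi_target))
  run <- cfg$run
  N <- if (!is.null(run$n_monomers)) run$n_monomers
       else if (!is.null(run$region_bp)) round(run$region_bp / cg$nu)
       else stop("run section requires `n_monomers` or `region_bp`")
  box <- box_for_phi(N, phi_target)
  geom <- solve_cg_geometry(preset, cg$nu / preset$nu0, box$phi_realized)
  kappa <- if (!is.null(cfg$model$kappa)) cfg$model$kappa
           else kappa_from_kuhn_ratio(geom$lk_b)
  model <- energy_model(
    kappa = kappa,
    E_i = if (!is.null(cfg$model$e_i) && cfg$model$e_i != 0) cfg$model$e_i else NULL,
    include_bonded_pairs = isTRUE(cfg$model$include_bonded_pairs))
  derived <- list(
    n = cg$nu / preset$nu0, N = N, S = box$S,
    phi_target = phi_target, phi_realized = box$phi_realized,
    b = geom$b, lk = geom$lk, lk_b = geom$lk_b,
    Nk = cg$nu * geom$lk_b, kappa = kappa,
    dc = default_dc(geom$b), d_kinetics = 2 * sqrt(2) * geom$b)
  out <- list(
    preset = preset, cg = cg, model = model,
    run = list(
      N = N,
      n_mcs = if (is.null(run$n_mcs)) 1e5 else run$n_mcs,
      snapshot_every = if (is.null(run$snapshot_every)) 1000L
                       else as.integer(run$snapshot_every),
      n_replicas = if (is.null(run$n_replicas)) 1L else as.integer(run$n_replicas),
      seed = if (is.null(run$seed)) 1L else as.integer(run$seed),
      init = if (is.null(run$init)) "hedgehog" else run$init,
      energy_check_every = if (is.null(run$energy_check_every)) 0L
                           else as.integer(run$energy_check_every)),
    io = cfg$io, derived = derived)
  out$manifest_hash <- .manifest_hash(out[c("preset", "cg", "run", "derived")])
  class(out) <- "run_config"
  out
}

#' @export
print.run_config <- function(x, ...) {
  d <- x$derived
  cat("<run_config> manifest", x$manifest_hash, "\n")
  cat(sprintf("  nu = %g bp (n = %g), N = %d, S = %d, Phi = %.4g (target %.4g)\n",
              x$cg$nu, d$n, d$N, d$S, d$phi_realized, d$phi_target))
  cat(sprintf("  b = %.4g nm, lk = %.4g nm (lk/b = %.4g), kappa = %.4g kT, Nk = %.4g bp\n",
              d$b, d$lk, d$lk_b, d$kappa, d$Nk))
  cat(sprintf("  run: %g MCS x %d replicas, snapshots every %d, seed %d\n",
              x$run$n_mcs, x$run$n_replicas, x$run$snapshot_every, x$run$seed))
  invisible(x)
}

# simulate the configured ensemble, optionally attaching states
.run_ensemble <- function(rc, states = NULL) {
  lat <- fcc_lattice(rc$derived$S, rc$derived$b)
  gen <- function(seed) init_conformation(rc$run$init, rc$derived$N, lat,
                                          seed = seed, states = states)
  cfg <- kmc_config(rc$run$n_mcs, rc$run$snapshot_every, rc$run$seed,
                    rc$run$energy_check_every)
  run_replicas(gen, rc$model, cfg, rc$run$n_replicas)
}

#' Amplitude-based intermediate fit window for g1
#'
#' Lower bound: the smallest lag whose g1 exceeds the squared Kuhn length
#' (local-stiffness regime equilibrated).  Upper bound: the largest lag
#' whose g1 is below half the phantom-chain end-to-end distance (well short
#' of the centre-of-mass regime), and in any case at most half the
#' trajectory span — beyond that, time-origin averaging rests on too few
#' independent origins for the estimate to be trusted (standard MSD
#' practice).
#'
#' @param g1 data.frame from [msd_monomer()].
#' @param lk Kuhn length, nm.
#' @param R2_chain squared chain size, nm^2 (e.g. [phantom_end_to_end()]).
#' @return `c(lo, hi)` in MCS, or `NULL` if the window is empty or spans
#'   less than half a decade.
#' @export
g1_fit_window <- function(g1, lk, R2_chain) {
  span <- max(g1$lag_mcs)
  ok_lo <- g1$lag_mcs[g1$value >= lk^2]
  ok_hi <- g1$lag_mcs[g1$value <= R2_chain / 2 & g1$lag_mcs <= span / 2]
  if (!length(ok_lo) || !length(ok_hi)) return(NULL)
  w <- c(min(ok_lo), max(ok_hi))
  if (w[2] / w[1] < 2.5) return(NULL)   # need a usable stretch of lags
  w
}

#' Null-model workflow: simulate and measure generic polymer behaviour
#'
#' Runs the configured replica ensemble, computes g1, g3, the internal
#' distance moments and the contact probability, and fits the power-law
#' exponents on amplitude-declared windows.  If a usable fit window cannot
#' be determined (run too short), the exponent is reported as `NA` with a
#' flag rather than fitted on an arbitrary range.
#'
#' @param rc a [resolve_config()] result.
#' @param pc_fit_decade separation decade `c(lo, hi)` (monomers) for the
#'   contact-probability exponent (default 10-100).
#' @return list with `trajectories`, `g1`, `g3`, `R2`, `pc`, and `fits`.
#' @export
workflow_null_model <- function(rc, pc_fit_decade = c(10, 100)) {
  trajs <- .run_ensemble(rc)
  g1 <- msd_monomer(trajs)
  g3 <- msd_com(trajs)
  window <- c(rc$run$n_mcs / 2, rc$run$n_mcs)   # late-time structure
  R2 <- distance_moments(trajs, window = window, nu = rc$cg$nu)
  pc <- contact_probability(trajs, window = window, dc = rc$derived$dc,
                            nu = rc$cg$nu)
  R2_chain <- phantom_end_to_end(rc$derived$N, rc$derived$kappa, rc$derived$b)
  w <- g1_fit_window(g1, rc$derived$lk, R2_chain)
  fits <- list(
    g1 = if (is.null(w)) list(exponent = NA_real_,
                              note = "insufficient fit window")
         else c(fit_power_law(g1, w), list(note = NA_character_)),
    pc = tryCatch(fit_power_law(pc, pc_fit_decade),
                  error = function(e) list(exponent = NA_real_,
                                           note = conditionMessage(e))))
  list(config = rc, trajectories = trajs, g1 = g1, g3 = g3, R2 = R2,
       pc = pc, fits = fits)
}

#' Copolymer workflow: epigenome-decorated simulation and contact analysis
#'
#' Attaches per-monomer epigenomic states, runs the ensemble with the
#' configured same-state interaction, and computes the windowed contact
#' map, state-resolved contact probabilities, the intra/inter enrichment
#' time course, and (optionally) pair-contact kinetics.
#'
#' @param rc a [resolve_config()] result (model should carry `E_i`).
#' @param states per-monomer state vector (length `N`), e.g. from
#'   [load_epigenome()] or [synthetic_epigenome()].
#' @param map_window MCS range for the averaged contact map (default: all).
#' @param kinetics_pairs 2-column matrix of monomer index pairs to track,
#'   or `NULL` to skip the kinetics stage.
#' @return list with `trajectories`, `map`, `pc_states`, `ratios`,
#'   `kinetics`.
#' @export
workflow_copolymer <- function(rc, states, map_window = c(0, Inf),
                               kinetics_pairs = NULL) {
  stopifnot(length(states) == rc$derived$N)
  trajs <- .run_ensemble(rc, states = states)
  map <- contact_map(trajs, window = map_window, dc = rc$derived$dc)
  pcs <- pc_by_state(trajs, window = map_window, dc = rc$derived$dc,
                     nu = rc$cg$nu)
  ratios <- ratio_timecourse(trajs, dc = rc$derived$dc, nu = rc$cg$nu)
  kin <- NULL
  if (!is.null(kinetics_pairs) && nrow(kinetics_pairs) > 0) {
    kin <- lapply(seq_len(nrow(kinetics_pairs)), function(r)
      ensemble_kinetics(trajs, kinetics_pairs[r, 1], kinetics_pairs[r, 2],
                        threshold = rc$derived$d_kinetics))
  } else {
    message("kinetics stage skipped: no pairs declared")
  }
  list(config = rc, trajectories = trajs, map = map, pc_states = pcs,
       ratios = ratios, kinetics = kin)
}
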
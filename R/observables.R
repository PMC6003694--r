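#' @rdname contact_probability
#' @export
default_dc <- function(b) sqrt(2) * b

# log-spaced subset of available snapshot lags (in snapshot units)
.default_lag_idx <- function(n_avail, n_lags = 40) {
  unique(round(exp(seq(log(1), log(n_avail), length.out = min(n_lags, n_avail)))))
}

.msd_one <- function(coords, lag_idx, a, com = FALSE) {
  # coords: N x 3 x T unwrapped grid units
  if (com) {
    cm <- apply(coords, c(2, 3), mean)          # 3 x T
    coords <- array(cm, dim = c(1, 3, ncol(cm)))
  }
  T_ <- dim(coords)[3]
  vapply(lag_idx, function(l) {
    d <- coords[, , (1 + l):T_, drop = FALSE] - coords[, , 1:(T_ - l), drop = FALSE]
    sum(d * d) / (dim(coords)[1] * (T_ - l)) * a^2
  }, numeric(1))
}

.msd_series <- function(trajs, lags, com) {
  if (inherits(trajs, "chrom_trajectory")) trajs <- list(trajs)
  mcs_grid <- trajs[[1]]$mcs
  cadence <- trajs[[1]]$config$snapshot_every
  T_ <- length(mcs_grid)
  if (is.null(lags)) {
    lag_idx <- .default_lag_idx(T_ - 1)
  } else {
    lag_idx <- unique(round(lags / cadence))
    dropped <- lag_idx < 1 | lag_idx > T_ - 1
    if (any(dropped)) {
      warning(sum(dropped), " lag(s) outside the trajectory span dropped")
      lag_idx <- lag_idx[!dropped]
    }
    if (!length(lag_idx)) stop("no usable lags")
  }
  per_rep <- vapply(trajs, function(tr)
    .msd_one(tr$coords, lag_idx, tr$lattice$a, com = com),
    numeric(length(lag_idx)))
  per_rep <- matrix(per_rep, nrow = length(lag_idx))
  R <- ncol(per_rep)
  value <- rowMeans(per_rep)
  stderr <- if (R >= 2) apply(per_rep, 1, stats::sd) / sqrt(R) else rep(NA_real_, length(lag_idx))
  data.frame(lag_mcs = lag_idx * cadence, value = value, stderr = stderr,
             n = R * (T_ - lag_idx))
}

#' Mean squared displacement of individual monomers (g1)
#'
#' Average over monomers, all time origins on the snapshot grid, and
#' replicas of \eqn{|r_i(t_0 + t) - r_i(t_0)|^2}, computed on unfolded
#' coordinates.  Standard errors are taken across replicas (per-replica
#' blocking), so overlapping-origin correlation is reflected honestly.
#'
#' @param trajs a `chrom_trajectory` or list of them (same grid).
#' @param lags lag times in MCS (rounded to the snapshot cadence), or `NULL`
#'   for a log-spaced default.
#' @return data.frame with `lag_mcs`, `value` (nm^2), `stderr`, `n`.
#' @export
msd_monomer <- function(trajs, lags = NULL) .msd_series(trajs, lags, com = FALSE)

#' Mean squared displacement of the chain centre of mass (g3)
#'
#' @inheritParams msd_monomer
#' @return data.frame with `lag_mcs`, `value` (nm^2), `stderr`, `n`.
#' @export
msd_com <- function(trajs, lags = NULL) .msd_series(trajs, lags, com = TRUE)

# shared pair-statistics pooling across replicas
.pair_stats <- function(trajs, window, dc, use_states = FALSE) {
  if (inherits(trajs, "chrom_trajectory")) trajs <- list(trajs)
  lapply(trajs, function(tr) {
    frames <- which(tr$mcs >= window[1] & tr$mcs <= window[2]) - 1L
    if (!length(frames)) stop("empty window: no snapshots in [",
                              window[1], ", ", window[2], "] MCS")
    N <- dim(tr$coords)[1]
    codes <- if (use_states && !is.null(tr$states))
      as.integer(factor(tr$states)) else integer(0)
    cpp_pair_stats(as.integer(tr$coords), N, as.integer(frames),
                   tr$lattice$a, dc, codes)
  })
}

.pool <- function(stats_list, num, den) {
  n <- Reduce(`+`, lapply(stats_list, `[[`, den))
  v <- Reduce(`+`, lapply(stats_list, `[[`, num))
  ifelse(n > 0, v / n, NA_real_)
}

.replica_stderr <- function(stats_list, num, den) {
  if (length(stats_list) < 2) return(NULL)
  len <- length(stats_list[[1]][[num]])
  per <- vapply(stats_list, function(s)
    ifelse(s[[den]] > 0, s[[num]] / s[[den]], NA_real_),
    numeric(len))
  per <- matrix(per, nrow = len)
  apply(per, 1, stats::sd, na.rm = TRUE) / sqrt(length(stats_list))
}

#' Internal-distance moments along the chain
#'
#' First and second moments of the squared spatial distance between monomer
#' pairs at genomic separation `s`:
#' \eqn{\langle R^2(s)\rangle} and
#' \eqn{\sigma^2(s) = \langle R^4(s)\rangle - \langle R^2(s)\rangle^2},
#' averaged over pairs, snapshots in the window, and replicas.
#'
#' @param trajs a `chrom_trajectory` or list of them.
#' @param window MCS range `c(t_min, t_max)` of snapshots to use (default:
#'   all).
#' @param nu bp per monomer; if given, an `s_bp` column is added.
#' @return data.frame with `s` (monomers), `R2` (nm^2), `sigma2` (nm^4),
#'   `stderr_R2`, `n`.
#' @export
distance_moments <- function(trajs, window = c(0, Inf), nu = NULL) {
  st <- .pair_stats(trajs, window, dc = 1e-9)
  R2 <- .pool(st, "sumR2", "n")
  R4 <- .pool(st, "sumR4", "n")
  n <- Reduce(`+`, lapply(st, `[[`, "n"))
  se <- .replica_stderr(st, "sumR2", "n")
  out <- data.frame(s = seq_along(R2), R2 = R2, sigma2 = R4 - R2^2,
                    stderr_R2 = if (is.null(se)) NA_real_ else se, n = n)
  out <- rbind(data.frame(s = 0, R2 = 0, sigma2 = 0, stderr_R2 = 0,
                          n = out$n[1]), out)
  if (!is.null(nu)) out$s_bp <- out$s * nu
  out
}

#' Contact probability versus genomic separation
#'
#' Fraction of (pair, snapshot) samples at separation `s` whose 3D distance
#' is strictly less than the threshold `dc`.  `P_c(0) = 1` by convention.
#' The default threshold is \eqn{\sqrt 2\, b} (the fcc cubic-cell edge),
#' which generalises the contact definition across coarse-graining levels.
#'
#' @param trajs a `chrom_trajectory` or list of them.
#' @param window MCS range of snapshots to use.
#' @param dc contact threshold in nm (default `sqrt(2) * b`).
#' @param nu bp per monomer; if given, an `s_bp` column is added.
#' @return data.frame with `s`, `pc`, `stderr`, `n`.
#' @export
contact_probability <- function(trajs, window = c(0, Inf), dc = NULL,
                                nu = NULL) {
  if (inherits(trajs, "chrom_trajectory")) b <- trajs$lattice$b
  else b <- trajs[[1]]$lattice$b
  if (is.null(dc)) dc <- default_dc(b)
  stopifnot(dc > 0)
  st <- .pair_stats(trajs, window, dc = dc)
  pc <- .pool(st, "ncontact", "n")
  se <- .replica_stderr(st, "ncontact", "n")
  n <- Reduce(`+`, lapply(st, `[[`, "n"))
  out <- data.frame(s = seq_along(pc), pc = pc,
                    stderr = if (is.null(se)) NA_real_ else se, n = n)
  out <- rbind(data.frame(s = 0, pc = 1, stderr = 0, n = out$n[1]), out)
  if (!is.null(nu)) out$s_bp <- out$s * nu
  out
}

#' Least-squares power-law fit on log-log axes
#'
#' @param series data.frame whose first column is the abscissa; the value
#'   column is `value`, `pc`, or `R2` (first match).
#' @param fit_range abscissa range `c(lo, hi)` over which to fit.
#' @return list with `exponent`, `amplitude`, `stderr` (of the exponent),
#'   `n`, `fit_range`.
#' @export
fit_power_law <- function(series, fit_range) {
  xcol <- names(series)[1]
  ycol <- intersect(c("value", "pc", "R2"), names(series))[1]
  if (is.na(ycol)) stop("no value column found")
  x <- series[[xcol]]; y <- series[[ycol]]
  keep <- x >= fit_range[1] & x <= fit_range[2] & is.finite(y) & x > 0
  if (sum(keep) < 5) stop("need at least 5 points in the fit range")
  if (any(y[keep] <= 0)) stop("non-positive values in the fit range")
  lx <- log(x[keep]); ly <- log(y[keep])
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  sxx <- sum((lx - mean(lx))^2)
  se <- sqrt(sum(res^2) / (length(res) - 2) / sxx)
  list(exponent = unname(cf[2]), amplitude = exp(unname(cf[1])),
       stderr = se, n = sum(keep), fit_range = fit_range)
}

#' Map Monte Carlo steps to seconds from the g1 amplitude
#'
#' Matches the measured monomer MSD (converted to \eqn{\mu m^2}) to the
#' experimentally motivated reference \eqn{g_1(t) = A \sqrt{t}} with
#' \eqn{A = 0.01\ \mu m^2 s^{-1/2}}: the seconds-per-MCS factor \eqn{\tau}
#' minimises \eqn{\sum_{\log t} [\log g_1(t) - \log(A (\tau t)^{1/2})]^2},
#' which has the closed form \eqn{\tau = \exp(2\,\overline{\log g_1 - \log A
#' - \tfrac12 \log t})}.  If the measured local exponent in the window
#' deviates from 0.5, this reduces to an amplitude match at the window's
#' geometric midpoint; a note is attached.
#'
#' @param g1_series data.frame from [msd_monomer()] (`value` in nm^2, lags
#'   in MCS).
#' @param fit_window lag range in MCS, spanning at least one decade.
#' @param reference_amplitude reference amplitude, \eqn{\mu m^2 s^{-1/2}}.
#' @return list of class `time_mapping`: `sec_per_mcs`, `reference_amplitude`,
#'   `fit_window`, `local_exponent`, `exponent_note`.
#' @export
time_map <- function(g1_series, fit_window, reference_amplitude = 0.01) {
  keep <- g1_series$lag_mcs >= fit_window[1] &
          g1_series$lag_mcs <= fit_window[2] & g1_series$value > 0
  if (sum(keep) < 2) stop("fit window does not overlap the measured lags")
  t_mcs <- g1_series$lag_mcs[keep]
  if (max(t_mcs) / min(t_mcs) < 10)
    warning("fit window spans less than one decade")
  g1_um2 <- g1_series$value[keep] * 1e-6           # nm^2 -> um^2
  tau <- exp(2 * mean(log(g1_um2) - log(reference_amplitude) -
                        0.5 * log(t_mcs)))
  alpha <- tryCatch(
    fit_power_law(data.frame(lag_mcs = t_mcs, value = g1_um2),
                  range(t_mcs))$exponent,
    error = function(e) NA_real_)
  note <- if (is.finite(alpha) && abs(alpha - 0.5) > 0.05)
    sprintf(paste0("local exponent %.3f differs from 0.5; sec_per_mcs is an ",
                   "amplitude match at the window's geometric midpoint"), alpha)
  else NA_character_
  structure(list(sec_per_mcs = tau, reference_amplitude = reference_amplitude,
                 fit_window = fit_window, local_exponent = alpha,
                 exponent_note = note),
            class = "time_mapping")
}

#' @export
print.time_mapping <- function(x, ...) {
  cat(sprintf("<time_mapping> 1 MCS = %.4g s (window %g-%g MCS)\n",
              x$sec_per_mcs, x$fit_window[1], x$fit_window[2]))
  if (!is.na(x$exponent_note)) cat("  note:", x$exponent_note, "\n")
  invisible(x)
}
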
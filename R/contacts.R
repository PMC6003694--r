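#' Average contact map over a time window
#'
#' Symmetric contact-frequency matrix over monomer bins: the frequency in
#' cell (a, b) is the number of observed contacts (3D distance strictly
#' below `dc`) between monomers of bins a and b, divided by the number of
#' (pair, snapshot) samples for that cell — i.e. the per-pair contact
#' probability, averaged over snapshots in the window and replicas.
#'
#' @param trajs a `chrom_trajectory` or list of them.
#' @param window MCS range of snapshots to include.
#' @param dc contact threshold, nm (default `sqrt(2) * b`).
#' @param bin monomers per bin (default 1).
#' @return object of class `chrom_contact_map`: list with `freq`, `counts`,
#'   `pairs` (per-cell pair-sample counts), `bin`, `dc`, `window`,
#'   `n_frames`.
#' @export
contact_map <- function(trajs, window = c(0, Inf), dc = NULL, bin = 1L) {
  if (inherits(trajs, "chrom_trajectory")) trajs <- list(trajs)
  b <- trajs[[1]]$lattice$b
  if (is.null(dc)) dc <- default_dc(b)
  N <- dim(trajs[[1]]$coords)[1]
  nbin <- as.integer(ceiling(N / bin))
  counts <- matrix(0, nbin, nbin)
  n_frames <- 0L
  for (tr in trajs) {
    frames <- which(tr$mcs >= window[1] & tr$mcs <= window[2]) - 1L
    if (!length(frames)) stop("empty window for a trajectory")
    counts <- counts + cpp_contact_map(as.integer(tr$coords), N,
                                       as.integer(frames), tr$lattice$a,
                                       dc, as.integer(bin))
    n_frames <- n_frames + length(frames)
  }
  size <- tabulate((seq_len(N) - 1L) %/% bin + 1L, nbin)
  pairs_cell <- outer(size, size)
  diag(pairs_cell) <- size * (size - 1) / 2
  pairs <- pairs_cell * n_frames
  freq <- ifelse(pairs > 0, counts / pairs, NA_real_)
  structure(list(freq = freq, counts = counts, pairs = pairs, bin = bin,
                 dc = dc, window = window, n_frames = n_frames),
            class = "chrom_contact_map")
}

#' @export
print.chrom_contact_map <- function(x, ...) {
  cat(sprintf("<chrom_contact_map> %d x %d bins (%d monomers/bin), dc = %.4g nm, %d frames\n",
              nrow(x$freq), ncol(x$freq), x$bin, x$dc, x$n_frames))
  invisible(x)
}

#' Write a contact map as dense TSV or sparse triplets
#'
#' @param map a `chrom_contact_map`.
#' @param path file path.
#' @param format `"dense"` (matrix TSV) or `"triplet"` (bin_i, bin_j,
#'   value for the upper triangle).
#' @export
write_contact_map <- function(map, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(map$freq, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    ut <- which(upper.tri(map$freq, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(bin_i = ut[, 1], bin_j = ut[, 2],
                     value = map$freq[ut])
    df <- df[is.finite(df$value) & df$value > 0, ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Contact probability split by epigenomic state
#'
#' Computes, on a common separation grid, the sequence-average contact
#' probability `pc` over all pairs, plus `p_intra` over same-state pairs and
#' `p_inter` over different-state pairs.  Separations with no same-state (or
#' no different-state) pairs are masked (`NA`).  The pair-count-weighted
#' average of `p_intra` and `p_inter` equals `pc` exactly.
#'
#' @param trajs a `chrom_trajectory` or list of them (with states).
#' @param window MCS range of snapshots.
#' @param dc contact threshold, nm (default `sqrt(2) * b`).
#' @param nu bp per monomer; adds `s_bp` if given.
#' @return data.frame with `s`, `pc`, `p_intra`, `p_inter`, `n`, `n_intra`,
#'   `n_inter`.
#' @export
pc_by_state <- function(trajs, window = c(0, Inf), dc = NULL, nu = NULL) {
  if (inherits(trajs, "chrom_trajectory")) trajs <- list(trajs)
  if (is.null(trajs[[1]]$states)) stop("trajectories carry no states")
  if (is.null(dc)) dc <- default_dc(trajs[[1]]$lattice$b)
  st <- .pair_stats(trajs, window, dc = dc, use_states = TRUE)
  out <- data.frame(
    s = seq_along(st[[1]]$n),
    pc = .pool(st, "ncontact", "n"),
    p_intra = .pool(st, "c_intra", "n_intra"),
    p_inter = .pool(st, "c_inter", "n_inter"),
    n = Reduce(`+`, lapply(st, `[[`, "n")),
    n_intra = Reduce(`+`, lapply(st, `[[`, "n_intra")),
    n_inter = Reduce(`+`, lapply(st, `[[`, "n_inter")))
  if (!is.null(nu)) out$s_bp <- out$s * nu
  out
}

#' Time course of intra- and inter-state contact enrichment
#'
#' At each recorded time, computes the band-averaged ratios
#' \eqn{\langle P_{intra}/P_c\rangle} and
#' \eqn{\langle P_{inter}/P_c\rangle}: contacts are pooled over replicas
#' at each separation `s`, the ratio of the same-state (or different-state)
#' contact probability to the sequence-average probability is formed per
#' `s`, and the ratios are averaged over the separations in each band.
#' Separations with no contacts or no same-state (different-state) pairs at
#' a given time are excluded from that time's average.
#'
#' @param trajs a `chrom_trajectory` or list of them (with states, common
#'   snapshot grid).
#' @param dc contact threshold, nm (default `sqrt(2) * b`).
#' @param bands 2-column matrix of separation bands in monomers (inclusive),
#'   or `NULL` for the defaults 10-100 kbp, 100 kbp - 1 Mbp, 1 - 10 Mbp
#'   converted via `nu`.
#' @param nu bp per monomer (needed for the default bands).
#' @return data.frame with `mcs`, `band` (label), `ratio_intra`,
#'   `ratio_inter`.
#' @export
ratio_timecourse <- function(trajs, dc = NULL, bands = NULL, nu = NULL) {
  if (inherits(trajs, "chrom_trajectory")) trajs <- list(trajs)
  if (is.null(trajs[[1]]$states)) stop("trajectories carry no states")
  if (is.null(dc)) dc <- default_dc(trajs[[1]]$lattice$b)
  if (is.null(bands)) {
    if (is.null(nu)) stop("give `nu` to use the default bands")
    bands <- rbind(c(1e4, 1e5), c(1e5, 1e6), c(1e6, 1e7)) / nu
    bands[, 1] <- pmax(1, ceiling(bands[, 1]))
    bands[, 2] <- floor(bands[, 2])
  }
  N <- dim(trajs[[1]]$coords)[1]
  bands <- bands[bands[, 1] <= pmin(bands[, 2], N - 1), , drop = FALSE]
  if (!nrow(bands)) stop("no band contains any pair")
  s_max <- min(N - 1, max(bands[, 2]))
  mcs <- trajs[[1]]$mcs
  agg <- NULL
  for (tr in trajs) {
    codes <- as.integer(factor(tr$states))
    res <- cpp_sep_contacts(as.integer(tr$coords), N,
                            as.integer(seq_along(mcs) - 1L),
                            tr$lattice$a, dc, codes, as.integer(s_max))
    if (is.null(agg)) agg <- res
    else for (nm in c("contacts_all", "contacts_intra"))
      agg[[nm]] <- agg[[nm]] + res[[nm]]
  }
  R <- length(trajs)
  p_all <- agg$pairs_all * R           # pair samples per s per time point
  p_intra <- agg$pairs_intra * R
  p_inter <- p_all - p_intra
  out <- do.call(rbind, lapply(seq_len(nrow(bands)), function(k) {
    ss <- seq(bands[k, 1], min(bands[k, 2], s_max))
    ri <- rin <- numeric(length(mcs))
    for (f in seq_along(mcs)) {
      pc_s <- agg$contacts_all[f, ss] / p_all[ss]
      pi_s <- ifelse(p_intra[ss] > 0,
                     agg$contacts_intra[f, ss] / p_intra[ss], NA)
      pe_s <- ifelse(p_inter[ss] > 0,
                     (agg$contacts_all[f, ss] - agg$contacts_intra[f, ss]) /
                       p_inter[ss], NA)
      ok <- pc_s > 0
      ri[f] <- mean((pi_s / pc_s)[ok], na.rm = TRUE)
      rin[f] <- mean((pe_s / pc_s)[ok], na.rm = TRUE)
    }
    data.frame(mcs = mcs, band = sprintf("%g-%g", bands[k, 1], bands[k, 2]),
               ratio_intra = ri, ratio_inter = rin)
  }))
  rownames(out) <- NULL
  out
}

#' Distance time series between two monomers
#'
#' @param traj a `chrom_trajectory`.
#' @param i,j monomer indices (1-based).
#' @param sec_per_mcs optional time mapping; if given, time is in seconds.
#' @return data.frame with `time` (MCS or s) and `distance` (nm).
#' @export
pair_distance_series <- function(traj, i, j, sec_per_mcs = NULL) {
  d <- traj$coords[i, , ] - traj$coords[j, , ]
  dist <- sqrt(colSums(d^2)) * traj$lattice$a
  t <- traj$mcs
  if (!is.null(sec_per_mcs)) t <- t * sec_per_mcs
  data.frame(time = t, distance = dist)
}

#' Pair-contact kinetics from a distance time series
#'
#' From a regularly sampled distance series, extracts the time of first
#' encounter `tau_first` (first sample strictly below the threshold,
#' censored at the series span if never reached), the contact times `tau_c`
#' (durations of maximal runs below the threshold) and the search times
#' `tau_s` (gaps between two consecutive contact runs).  Durations are in
#' the series' time units; with sampling interval `dt`, a run of `k`
#' samples lasts `k * dt` and `tau_first` is the time elapsed before the
#' first below-threshold sample.  The durations satisfy
#' `tau_first + sum(tau_c) + sum(tau_s) + trailing = span` exactly.
#'
#' @param distance_series data.frame with `time` and `distance` (regular
#'   sampling).
#' @param threshold contact distance, same units as `distance`.
#' @return list of class `contact_kinetics`: `tau_first`, `censored`,
#'   `tau_c`, `tau_s`, `trailing`, `span`, `threshold`.
#' @export
pair_kinetics <- function(distance_series, threshold) {
  t <- distance_series$time
  d <- distance_series$distance
  n <- length(t)
  dt <- if (n > 1) (t[n] - t[1]) / (n - 1) else 1
  span <- n * dt
  below <- d < threshold
  if (!any(below)) {
    return(structure(list(tau_first = span, censored = TRUE,
                          tau_c = numeric(0), tau_s = numeric(0),
                          trailing = 0, span = span, threshold = threshold),
                     class = "contact_kinetics"))
  }
  r <- rle(below)
  lens <- r$lengths * dt
  first_below <- which(r$values)[1]
  tau_first <- if (first_below == 1) 0 else lens[1]
  below_runs <- which(r$values)
  tau_c <- lens[below_runs]
  # search times: above-runs strictly between two below-runs
  above_runs <- which(!r$values)
  interior <- above_runs[above_runs > min(below_runs) &
                         above_runs < max(below_runs)]
  tau_s <- lens[interior]
  trailing <- if (max(below_runs) < length(lens))
    sum(lens[seq(max(below_runs) + 1, length(lens))]) else 0
  structure(list(tau_first = tau_first, censored = FALSE, tau_c = tau_c,
                 tau_s = tau_s, trailing = trailing, span = span,
                 threshold = threshold),
            class = "contact_kinetics")
}

#' Kinetics over an ensemble of trajectories for one locus pair
#'
#' @param trajs list of `chrom_trajectory`.
#' @param i,j monomer indices.
#' @param threshold contact distance in nm; default `2 * sqrt(2) * b`, the
#'   pair-tracking threshold scaled to the lattice.
#' @param sec_per_mcs optional time mapping.
#' @return list with `tau_first` (one per trajectory), `censored` (logical),
#'   `censored_fraction`, `tau_c`, `tau_s` (pooled), `threshold`.
#' @export
ensemble_kinetics <- function(trajs, i, j, threshold = NULL,
                              sec_per_mcs = NULL) {
  if (inherits(trajs, "chrom_trajectory")) trajs <- list(trajs)
  if (is.null(threshold)) threshold <- 2 * sqrt(2) * trajs[[1]]$lattice$b
  ks <- lapply(trajs, function(tr)
    pair_kinetics(pair_distance_series(tr, i, j, sec_per_mcs), threshold))
  list(tau_first = vapply(ks, `[[`, numeric(1), "tau_first"),
       censored = vapply(ks, `[[`, logical(1), "censored"),
       censored_fraction = mean(vapply(ks, `[[`, logical(1), "censored")),
       tau_c = unlist(lapply(ks, `[[`, "tau_c")),
       tau_s = unlist(lapply(ks, `[[`, "tau_s")),
       threshold = threshold)
}

#' Pearson correlation between two contact maps
#'
#' Correlates matched upper-triangle entries of two maps on identical bin
#' grids, excluding a diagonal band of the given width and entries missing
#' in either map.
#'
#' @param map_a,map_b `chrom_contact_map` objects (or plain matrices) on the
#'   same grid.
#' @param exclude_diag number of diagonals to exclude (0 keeps off-diagonal
#'   entries only from distance 1 up; the main diagonal is always excluded).
#' @return Pearson correlation coefficient.
#' @export
map_correlation <- function(map_a, map_b, exclude_diag = 0) {
  A <- if (inherits(map_a, "chrom_contact_map")) map_a$freq else map_a
  B <- if (inherits(map_b, "chrom_contact_map")) map_b$freq else map_b
  if (!all(dim(A) == dim(B))) stop("contact maps are on different grids")
  idx <- which(upper.tri(A) & (col(A) - row(A)) > exclude_diag)
  keep <- is.finite(A[idx]) & is.finite(B[idx])
  stats::cor(A[idx][keep], B[idx][keep])
}
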
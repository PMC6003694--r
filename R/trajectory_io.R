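#' Write / read a trajectory as columnar text
#'
#' Long-format TSV: one row per (snapshot, monomer) with the unwrapped grid
#' coordinates; a commented header carries the lattice (`S`, `b`), the
#' snapshot cadence, the seed, the acceptance rate, and the per-monomer
#' states.  Suited to the CLI workflow; within R, keep trajectories as the
#' in-memory objects returned by [kmc_run()].
#'
#' @param traj a `chrom_trajectory`.
#' @param path file path.
#' @return `write_trajectory_tsv` returns `path` invisibly;
#'   `read_trajectory_tsv` returns the trajectory.
#' @export
write_trajectory_tsv <- function(traj, path) {
  N <- dim(traj$coords)[1]
  T_ <- dim(traj$coords)[3]
  hdr <- c(sprintf("# S=%d", traj$lattice$S),
           sprintf("# b=%.17g", traj$lattice$b),
           sprintf("# N=%d", N),
           sprintf("# snapshot_every=%d", traj$config$snapshot_every),
           sprintf("# seed=%d", traj$config$seed),
           sprintf("# acceptance=%.17g", traj$acceptance_rate),
           sprintf("# states=%s",
                   if (is.null(traj$states)) "."
                   else paste(traj$states, collapse = ",")),
           "# mcs monomer x y z energy")
  flat <- matrix(aperm(traj$coords, c(1, 3, 2)), nrow = N * T_)
  df <- data.frame(mcs = rep(traj$mcs, each = N),
                   monomer = rep(seq_len(N), T_),
                   flat,
                   energy = rep(traj$energy, each = N))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  hdr <- readLines(path, n = 7)
  get_field <- function(key) sub(paste0("# ", key, "="), "",
                                 hdr[grepl(paste0("^# ", key, "="), hdr)])
  S <- as.integer(get_field("S"))
  b <- as.numeric(get_field("b"))
  N <- as.integer(get_field("N"))
  cadence <- as.integer(get_field("snapshot_every"))
  seed <- as.integer(get_field("seed"))
  acc <- as.numeric(get_field("acceptance"))
  states_raw <- get_field("states")
  states <- if (states_raw == ".") NULL else strsplit(states_raw, ",")[[1]]
  df <- utils::read.table(path, comment.char = "#", sep = "\t")
  T_ <- nrow(df) / N
  ord <- order(df[[1]], df[[2]])
  df <- df[ord, ]
  coords <- array(0L, dim = c(N, 3, T_))
  for (d in 1:3) coords[, d, ] <- matrix(as.integer(df[[2 + d]]), N, T_)
  structure(list(coords = coords, mcs = unique(df[[1]]),
                 energy = df[[6]][seq(1, nrow(df), by = N)],
                 acceptance_rate = acc, audit_max_error = NA_real_,
                 lattice = fcc_lattice(S, b), states = states, model = NULL,
                 config = list(snapshot_every = cadence, seed = seed)),
            class = "chrom_trajectory")
}
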
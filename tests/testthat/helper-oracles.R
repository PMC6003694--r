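# Independent reference implementations used as oracles in the tests.
# These deliberately use brute force / enumeration and stay independent of
# the package's own code paths.

# Boltzmann average of cos(theta) over the 12 fcc directions relative to a
# fixed previous bond, with per-angle energy kappa * (1 - cos theta).
enum_mean_cos <- function(kappa) {
  cosv <- c(1, 0.5, 0, -0.5, -1)
  mult <- c(1, 4, 2, 4, 1)
  w <- mult * exp(-kappa * (1 - cosv))
  sum(cosv * w) / sum(w)
}

# the 12 fcc nearest-neighbour offsets in grid units
offsets12 <- function() {
  rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
        c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
        c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
}

# Monte-Carlo sampler of the 13-state phantom stored-length chain: each
# bond is zero-length with probability 1/13 (resetting the direction
# memory); otherwise its direction is drawn among the 12 lattice directions
# with Boltzmann weight exp(-kappa (1 - cos theta)) relative to the last
# bond if that bond was non-zero, uniformly otherwise.
phantom_chain_mc <- function(N, kappa, n_samples, seed = 42) {
  set.seed(seed)
  off <- offsets12()
  cos_tab <- tcrossprod(off) / 2       # 12 x 12 cos(theta)
  W <- exp(-kappa * (1 - cos_tab))
  n_bonds <- N - 1
  pos <- matrix(0, n_samples, 3)
  prev <- sample.int(12, n_samples, replace = TRUE)   # first bond uniform
  zero1 <- stats::runif(n_samples) < 1 / 13
  pos <- pos + off[prev, ] * (!zero1)
  prev[zero1] <- 0L   # 0 encodes "no direction memory"
  if (n_bonds >= 2) {
    for (k in 2:n_bonds) {
      cur <- integer(n_samples)
      fresh <- prev == 0L
      if (any(fresh)) cur[fresh] <- sample.int(12, sum(fresh), replace = TRUE)
      for (d in 1:12) {
        idx <- which(prev == d)
        if (length(idx))
          cur[idx] <- sample.int(12, length(idx), replace = TRUE, prob = W[d, ])
      }
      zero <- stats::runif(n_samples) < 1 / 13
      pos <- pos + off[cur, ] * (!zero)
      cur[zero] <- 0L
      prev <- cur
    }
  }
  re2 <- rowSums(pos^2) / 2            # grid units^2 -> b^2 (|offset|^2 = 2)
  list(mean = mean(re2), se = stats::sd(re2) / sqrt(n_samples))
}

# brute-force double-loop energy evaluator: bending kappa(1 - cos) per
# angle between consecutive non-zero bonds, plus U[e(i), e(j)] for every
# |i - j| >= 2 pair on nearest-neighbour sites (minimum image)
reference_energy <- function(conf, kappa, U = NULL) {
  lat <- conf$lattice
  n <- nrow(conf$pos)
  upos <- conf$pos + conf$img * lat$twoS
  e <- 0
  if (n >= 3 && kappa != 0) {
    for (j in 2:(n - 1)) {
      u <- upos[j, ] - upos[j - 1, ]
      v <- upos[j + 1, ] - upos[j, ]
      if (all(u == 0) || all(v == 0)) next
      e <- e + kappa * (1 - sum(u * v) / 2)
    }
  }
  if (!is.null(U) && length(U)) {
    codes <- match(as.character(conf$states), rownames(U))
    for (i in 1:(n - 1)) {
      for (j in (i + 2):n) {
        if (j > n) break
        d <- conf$pos[j, ] - conf$pos[i, ]
        d <- d - lat$twoS * round(d / lat$twoS)
        if (all(abs(d) <= 1) && sum(abs(d)) == 2)
          e <- e + U[codes[i], codes[j]]
      }
    }
  }
  e
}

# straight chain of N monomers along the (1,1,0) direction
straight_conf <- function(N, lattice) {
  m <- lattice$twoS
  stopifnot(N <= m - 2)
  pos <- cbind(2L + seq_len(N) - 1L, 2L + seq_len(N) - 1L, 2L)
  conformation(pos, lattice)
}

# wrap plain coordinate arrays as a minimal trajectory object for the
# observable functions (N x 3 x T, unwrapped grid units)
fake_traj <- function(coords, lattice, mcs = NULL, states = NULL,
                      snapshot_every = 1L) {
  T_ <- dim(coords)[3]
  structure(list(coords = coords, mcs = if (is.null(mcs)) seq_len(T_) - 1 else mcs,
                 energy = rep(0, T_), acceptance_rate = NA_real_,
                 audit_max_error = 0, lattice = lattice, states = states,
                 model = NULL,
                 config = list(snapshot_every = snapshot_every)),
            class = "chrom_trajectory")
}
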
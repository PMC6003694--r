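#' Polymer conformation on the fcc lattice
#'
#' A conformation stores, per monomer, the wrapped grid coordinates, the
#' integer box-image vector (so that unfolded coordinates are
#' `(pos + img * 2S) * a`), and optionally an epigenomic state label.  Bonds
#' between consecutive monomers are either a nearest-neighbour step (length
#' `b`) or zero length: two consecutive monomers may share a site, storing
#' one bond length of slack at that node ("stored length").  Non-consecutive
#' monomers can never share a site.
#'
#' @param pos integer N x 3 matrix of wrapped grid coordinates.
#' @param lattice an [fcc_lattice()].
#' @param img integer N x 3 matrix of box images (default all zero).
#' @param states optional character/factor vector of per-monomer states.
#' @param seed optional seed recorded for provenance.
#' @return an object of class `chrom_conformation`.
#' @export
conformation <- function(pos, lattice, img = NULL, states = NULL, seed = NULL) {
  stopifnot(inherits(lattice, "fcc_lattice"), ncol(pos) == 3)
  storage.mode(pos) <- "integer"
  if (is.null(img)) img <- matrix(0L, nrow(pos), 3) else storage.mode(img) <- "integer"
  stopifnot(all(dim(img) == dim(pos)))
  if (!is.null(states)) stopifnot(length(states) == nrow(pos))
  structure(list(pos = pos, img = img, states = states,
                 lattice = lattice, seed = seed),
            class = "chrom_conformation")
}

#' @export
print.chrom_conformation <- function(x, ...) {
  cat(sprintf("<chrom_conformation> N = %d on S = %d box (b = %.4g nm)",
              nrow(x$pos), x$lattice$S, x$lattice$b))
  stored <- sum(rowSums(abs(diff(x$pos) - x$lattice$twoS *
                              round(diff(x$pos) / x$lattice$twoS))) == 0)
  cat(sprintf(", %d stored-length bonds\n", stored))
  if (!is.null(x$states))
    cat("  states:", paste(utils::head(unique(x$states), 6), collapse = ", "), "\n")
  invisible(x)
}

#' Number of monomers
#' @param conf a `chrom_conformation`.
#' @return integer.
#' @export
n_monomers <- function(conf) nrow(conf$pos)

#' Validate a conformation against the lattice-chain rules
#'
#' Checks, monomer by monomer: grid coordinates on the lattice (even parity,
#' in range); connectivity (each bond a zero or nearest-neighbour step under
#' the minimum image); occupancy (no site holds more than two monomers, and
#' a doubly occupied site holds only consecutive monomers).
#'
#' @param conf a [conformation()].
#' @return character vector of violations (empty if valid), each naming the
#'   monomer index and the broken rule.
#' @export
validate_conformation <- function(conf) {
  lat <- conf$lattice
  pos <- conf$pos
  n <- nrow(pos)
  bad <- character(0)
  oob <- which(pos < 0 | pos >= lat$twoS, arr.ind = TRUE)
  if (length(oob)) bad <- c(bad, sprintf("monomer %d: range", unique(oob[, 1])))
  parity <- which(rowSums(pos) %% 2L != 0L)
  if (length(parity)) bad <- c(bad, sprintf("monomer %d: parity", parity))
  if (length(bad)) return(bad)
  if (n > 1) {
    d <- grid_min_image(diff(pos), lat$twoS)
    ok <- apply(d, 1, function(v) all(abs(v) <= 1) && sum(abs(v)) %in% c(0L, 2L))
    if (any(!ok)) bad <- c(bad, sprintf("monomer %d: connectivity", which(!ok)))
    # image bookkeeping: unfolded bond must equal the minimum-image bond
    du <- diff(pos + conf$img * lat$twoS)
    if (any(du != d)) {
      off <- unique(which(rowSums(du != d) > 0))
      bad <- c(bad, sprintf("monomer %d: image", off))
    }
  }
  ids <- site_id(lat, pos)
  tab <- split(seq_len(n), ids)
  for (occ in tab) {
    if (length(occ) > 2)
      bad <- c(bad, sprintf("monomer %d: occupancy", occ[1]))
    else if (length(occ) == 2 && diff(occ) != 1L)
      bad <- c(bad, sprintf("monomer %d: occupancy", occ[1]))
  }
  bad
}

#' Unfolded real-space coordinates
#'
#' Applies the accumulated box images so that chains may extend over
#' arbitrary distances; bonded distances are exactly 0 or `b`.
#'
#' @param conf a [conformation()].
#' @return numeric N x 3 matrix of coordinates in nm.
#' @export
unfold <- function(conf) {
  (conf$pos + conf$img * conf$lattice$twoS) * conf$lattice$a
}

#' Re-wrap unfolded grid coordinates into a conformation
#'
#' @param grid integer N x 3 matrix of unwrapped grid coordinates.
#' @param lattice an [fcc_lattice()].
#' @param states optional per-monomer states.
#' @return a [conformation()].
#' @export
refold <- function(grid, lattice, states = NULL) {
  img <- floor(grid / lattice$twoS)
  conformation(grid - img * lattice$twoS, lattice,
               img = matrix(as.integer(img), nrow(grid), 3), states = states)
}

#' Initial conformations: hedgehog, line, random growth
#'
#' `hedgehog` grows a knot-free configuration: a short straight scaffold
#' through the box centre is extended by repeatedly picking a random bond
#' and inserting a new monomer either at an empty site that is a nearest
#' neighbour of both bond endpoints, or as stored length on a singly
#' occupied endpoint site.  Because every insertion is local, the growth
#' cannot thread the chain through itself, so the result is unknotted by
#' construction.  `line` is a straight path (doubling up monomers as stored
#' length if the chain is longer than the box traverse).  `random_collapse`
#' appends monomers at random legal neighbouring or stored-length positions
#' and may produce knotted, collapsed configurations (useful as a control).
#'
#' @param kind one of `"hedgehog"`, `"line"`, `"random_collapse"`.
#' @param N number of monomers; at most `2 * 4 S^3`.
#' @param lattice an [fcc_lattice()].
#' @param seed RNG seed (an integer) used for the growth; recorded in the
#'   returned conformation.
#' @param states optional per-monomer states to attach.
#' @param max_retries growth restarts before failing.
#' @return a valid [conformation()].
#' @export
init_conformation <- function(kind = c("hedgehog", "line", "random_collapse"),
                              N, lattice, seed = 1L, states = NULL,
                              max_retries = 10L) {
  kind <- match.arg(kind)
  stopifnot(N >= 1, N <= 2 * lattice$n_sites)
  if (!is.null(seed)) set.seed(seed)
  conf <- switch(kind,
    hedgehog = .grow_hedgehog(N, lattice, max_retries),
    line = .init_line(N, lattice),
    random_collapse = .grow_random(N, lattice, max_retries))
  conf$states <- states
  conf$seed <- seed
  conf
}

# short straight scaffold through the centre along the (1,1,0) fcc
# direction; kept short so the grown configuration is an isotropic compact
# ball rather than a box-spanning sausage
.scaffold <- function(N, lattice, scaffold_len = 8L) {
  m <- lattice$twoS
  len <- min(N, m, scaffold_len)
  c0 <- as.integer(m %/% 2)
  z0 <- if ((3L * c0) %% 2L == 0L) c0 else (c0 + 1L) %% m  # force even parity
  steps <- seq_len(len) - 1L
  pos <- cbind((c0 + steps) %% m, (c0 + steps) %% m, rep(z0, len))
  storage.mode(pos) <- "integer"
  img <- matrix(0L, len, 3)
  # keep images continuous if the scaffold wraps
  wrapped <- (c0 + steps) %/% m
  img[, 1] <- img[, 2] <- as.integer(wrapped)
  list(pos = pos, img = img)
}

.grow_hedgehog <- function(N, lattice, max_retries) {
  off <- fcc_offsets()
  m <- lattice$twoS
  for (attempt in seq_len(max_retries)) {
    sc <- .scaffold(N, lattice)
    len <- nrow(sc$pos)
    pos <- matrix(0L, N, 3); img <- matrix(0L, N, 3)
    pos[seq_len(len), ] <- sc$pos; img[seq_len(len), ] <- sc$img
    occ <- integer(m^3)
    occ[site_id(lattice, sc$pos)] <- occ[site_id(lattice, sc$pos)] + 1L
    stall <- 0L
    while (len < N) {
      j <- sample.int(len - 1L, 1L)        # bond (j, j+1)
      cand <- .insertion_sites(pos, img, j, occ, lattice, off)
      if (is.null(cand)) {
        stall <- stall + 1L
        if (stall > 200L * N) break
        next
      }
      pick <- cand[[sample.int(length(cand), 1L)]]
      # shift monomers j+1..len up by one and insert
      idx <- seq(j + 1L, len)
      pos[idx + 1L, ] <- pos[idx, , drop = FALSE]
      img[idx + 1L, ] <- img[idx, , drop = FALSE]
      pos[j + 1L, ] <- pick$pos
      img[j + 1L, ] <- pick$img
      occ[pick$sid] <- occ[pick$sid] + 1L
      len <- len + 1L
    }
    if (len == N)
      return(conformation(pos, lattice, img = img))
  }
  stop("hedgehog growth stalled after ", max_retries,
       " attempts; increase the box or reduce N")
}

# legal insertion positions between monomers j and j+1: empty common
# neighbours of both endpoints, or stored length on a singly occupied
# endpoint site
.insertion_sites <- function(pos, img, j, occ, lattice, off) {
  m <- lattice$twoS
  a_pos <- pos[j, ]; b_pos <- pos[j + 1L, ]
  # a stored-length bond admits no insertion: placing the new monomer on a
  # neighbour site would leave the two old monomers sharing a site while no
  # longer consecutive
  if (all(a_pos == b_pos)) return(NULL)
  cand <- list()
  sid_a <- site_id(lattice, matrix(a_pos, 1))
  sid_b <- site_id(lattice, matrix(b_pos, 1))
  if (occ[sid_a] == 1L)
    cand[[length(cand) + 1L]] <- list(pos = a_pos, img = img[j, ], sid = sid_a)
  if (occ[sid_b] == 1L)
    cand[[length(cand) + 1L]] <- list(pos = b_pos, img = img[j + 1L, ], sid = sid_b)
  # common nearest neighbours (minimum image relative to endpoint a)
  d_ab <- grid_min_image(matrix(b_pos - a_pos, 1), m)[1, ]
  for (r in seq_len(12)) {
    v <- off[r, ]
    # candidate q = a + v must also be NN (or same) of b: (v - d_ab) in {0, NN}
    w <- v - d_ab
    s <- sum(abs(w))
    if (!(s %in% c(0L, 2L)) || any(abs(w) > 1L)) next
    q_wrapped <- (a_pos + v) %% m
    sid_q <- site_id(lattice, matrix(q_wrapped, 1))
    if (occ[sid_q] != 0L) next
    q_img <- img[j, ] + (a_pos + v - q_wrapped) %/% m
    cand[[length(cand) + 1L]] <-
      list(pos = q_wrapped, img = as.integer(q_img), sid = sid_q)
  }
  if (length(cand) == 0L) NULL else cand
}

.init_line <- function(N, lattice) {
  m <- lattice$twoS
  traverse <- m   # distinct sites along the (1,1,0) direction before wrap
  per_site <- if (N <= traverse) 1L else 2L
  if (N > 2L * traverse)
    stop("line initialisation needs N <= 2 * 2S; use hedgehog instead")
  c0 <- as.integer(m %/% 2)
  site_idx <- (seq_len(N) - 1L) %/% per_site
  pos <- cbind((c0 + site_idx) %% m, (c0 + site_idx) %% m, rep(c0, N))
  if ((3L * c0) %% 2L != 0L) pos[, 3] <- (c0 + 1L) %% m
  storage.mode(pos) <- "integer"
  img <- matrix(0L, N, 3)
  img[, 1] <- img[, 2] <- as.integer((c0 + site_idx) %/% m)
  conformation(pos, lattice, img = img)
}

.grow_random <- function(N, lattice, max_retries) {
  off <- fcc_offsets()
  m <- lattice$twoS
  for (attempt in seq_len(max_retries)) {
    pos <- matrix(0L, N, 3); img <- matrix(0L, N, 3)
    c0 <- as.integer(m %/% 2)
    start <- c(c0, c0, if ((3L * c0) %% 2L == 0L) c0 else (c0 + 1L) %% m)
    pos[1, ] <- start
    occ <- integer(m^3)
    occ[site_id(lattice, matrix(start, 1))] <- 1L
    ok <- TRUE
    for (i in seq_len(N - 1L)) {
      prev <- pos[i, ]
      sid_prev <- site_id(lattice, matrix(prev, 1))
      choices <- sample.int(13L)   # 12 directions + stored length
      placed <- FALSE
      for (ch in choices) {
        if (ch == 13L) {
          if (occ[sid_prev] == 1L) {
            pos[i + 1L, ] <- prev; img[i + 1L, ] <- img[i, ]
            occ[sid_prev] <- 2L; placed <- TRUE; break
          }
        } else {
          v <- off[ch, ]
          q <- (prev + v) %% m
          sid_q <- site_id(lattice, matrix(q, 1))
          if (occ[sid_q] == 0L) {
            pos[i + 1L, ] <- q
            img[i + 1L, ] <- img[i, ] + (prev + v - q) %/% m
            occ[sid_q] <- 1L; placed <- TRUE; break
          }
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(conformation(pos, lattice, img = img))
  }
  stop("random growth stalled after ", max_retries, " attempts")
}

#' Write / read a conformation as columnar text
#'
#' Columns: monomer index, grid i, j, k, image x, y, z, state.  A commented
#' header records `S`, `b` and the seed.
#'
#' @param conf a [conformation()].
#' @param path file path.
#' @return `write_conformation` returns `path` invisibly;
#'   `read_conformation` returns the conformation.
#' @export
write_conformation <- function(conf, path) {
  hdr <- c(sprintf("# S=%d", conf$lattice$S),
           sprintf("# b=%.17g", conf$lattice$b),
           sprintf("# seed=%s", if (is.null(conf$seed)) "NA" else conf$seed),
           "# monomer i j k img_x img_y img_z state")
  df <- data.frame(monomer = seq_len(nrow(conf$pos)),
                   conf$pos, conf$img,
                   state = if (is.null(conf$states)) "." else as.character(conf$states))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_conformation
#' @export
read_conformation <- function(path) {
  hdr <- readLines(path, n = 4)
  S <- as.integer(sub("# S=", "", hdr[1]))
  b <- as.numeric(sub("# b=", "", hdr[2]))
  seed <- sub("# seed=", "", hdr[3])
  df <- utils::read.table(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  states <- if (all(df[[8]] == ".")) NULL else df[[8]]
  conformation(unname(as.matrix(df[, 2:4])), fcc_lattice(S, b),
               img = unname(as.matrix(df[, 5:7])), states = states,
               seed = if (seed == "NA") NULL else as.integer(seed))
}

#' Export unfolded coordinates in XYZ format (nm)
#'
#' @param conf a [conformation()].
#' @param path file path.
#' @param element symbol written per monomer (state label used if present).
#' @export
write_xyz <- function(conf, path, element = "C") {
  xyz <- unfold(conf)
  lab <- if (!is.null(conf$states)) as.character(conf$states)
         else rep(element, nrow(xyz))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(xyz)), "unfolded chromatin chain, nm"), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", lab, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}

#' Box size realising a target volume fraction
#'
#' Returns the integer box edge `S` (fcc cells) minimising
#' `|N / (4 S^3) - phi|`, plus the realised volume fraction; the realised
#' value is what should be fed back into [solve_cg_geometry()] so the
#' lattice actually simulated matches the theory.
#'
#' @param N number of monomers.
#' @param phi target lattice volume fraction.
#' @return list with `S` and `phi_realized`.
#' @export
box_for_phi <- function(N, phi) {
  stopifnot(N >= 1, phi > 0, phi <= 2)
  S_real <- (N / (4 * phi))^(1 / 3)
  cand <- unique(pmax(2L, c(floor(S_real), ceiling(S_real))))
  err <- abs(N / (4 * cand^3) - phi)
  S <- cand[which.min(err)]
  list(S = as.integer(S), phi_realized = N / (4 * S^3))
}
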
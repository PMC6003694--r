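#' Face-centred cubic lattice with periodic boundaries
#'
#' The lattice is embedded in the standard way as the even-parity sites of a
#' cubic grid: integer triples (i, j, k) with i + j + k even, grid spacing
#' \eqn{a = b/\sqrt 2} where `b` is the nearest-neighbour distance (the bond
#' length of the polymer).  A simulation box of `S` fcc unit cells per edge
#' spans `2S` grid units per axis and holds `4 S^3` sites.  The 12 nearest
#' neighbours of a site are the parity-preserving offsets with two non-zero
#' components equal to +/-1.
#'
#' @param S fcc unit cells per box edge, >= 2.
#' @param b nearest-neighbour (bond) distance, nm.
#' @return an object of class `fcc_lattice` with fields `S`, `twoS`, `b`,
#'   `a` (grid spacing, nm) and `n_sites`.
#' @examples
#' lat <- fcc_lattice(S = 4, b = 1)
#' lat$n_sites   # 256
#' @export
fcc_lattice <- function(S, b = 1) {
  stopifnot(S >= 2, S == round(S), b > 0)
  structure(list(S = as.integer(S), twoS = as.integer(2 * S), b = b,
                 a = b / sqrt(2), n_sites = 4L * as.integer(S)^3),
            class = "fcc_lattice")
}

#' @export
print.fcc_lattice <- function(x, ...) {
  cat(sprintf("<fcc_lattice> S = %d (%d sites), b = %.4g nm\n",
              x$S, x$n_sites, x$b))
  invisible(x)
}

# the 12 nearest-neighbour grid offsets, closed under negation
fcc_offsets <- function() {
  off <- rbind(
    c( 1,  1, 0), c( 1, -1, 0), c(-1,  1, 0), c(-1, -1, 0),
    c( 1, 0,  1), c( 1, 0, -1), c(-1, 0,  1), c(-1, 0, -1),
    c(0,  1,  1), c(0,  1, -1), c(0, -1,  1), c(0, -1, -1))
  storage.mode(off) <- "integer"
  off
}

#' Linear site id from grid coordinates
#'
#' Sites are numbered 1-based over the full cubic grid; only even-parity
#' triples are valid fcc sites.
#'
#' @param lattice an [fcc_lattice()].
#' @param ijk integer matrix (or vector) of grid coordinates in `[0, 2S)`.
#' @return integer site ids.
#' @export
site_id <- function(lattice, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  m <- lattice$twoS
  if (any(ijk < 0 | ijk >= m)) stop("grid coordinates out of range")
  if (any((rowSums(ijk) %% 2L) != 0L)) stop("odd-parity site: not on the fcc lattice")
  as.integer(ijk[, 1] * m^2 + ijk[, 2] * m + ijk[, 3] + 1L)
}

#' Grid coordinates from a linear site id
#' @param lattice an [fcc_lattice()].
#' @param id integer site ids.
#' @return integer matrix of grid coordinates.
#' @export
site_ijk <- function(lattice, id) {
  m <- lattice$twoS
  id0 <- as.integer(id) - 1L
  if (any(id0 < 0 | id0 >= m^3)) stop("invalid site id")
  cbind(i = id0 %/% m^2, j = (id0 %/% m) %% m, k = id0 %% m)
}

#' The 12 nearest neighbours of an fcc site
#'
#' @param lattice an [fcc_lattice()].
#' @param site a single site id.
#' @return integer vector of the 12 neighbouring site ids, periodic wrap
#'   applied.
#' @export
fcc_neighbors <- function(lattice, site) {
  ijk <- site_ijk(lattice, site)
  nb <- sweep(fcc_offsets(), 2, as.integer(ijk), "+") %% lattice$twoS
  site_id(lattice, nb)
}

# minimum-image difference of grid coordinate matrices (rows), components
# mapped to (-S, S] grid units
grid_min_image <- function(d, twoS) {
  d <- d - twoS * round(d / twoS)
  d
}
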
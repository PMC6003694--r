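#' Default mapping from raw annotation labels to the four merged states
#'
#' Five-colour chromatin-type annotations distinguish two euchromatic
#' (active) classes plus HP1-associated constitutive heterochromatin,
#' Polycomb-associated facultative heterochromatin, and the prevalent
#' "black" heterochromatin.  The two euchromatic classes are merged into a
#' single "active" state before assignment to monomers; already-merged
#' labels pass through.
#'
#' @return named character vector: raw label -> merged state.
#' @export
default_state_merge <- function() {
  c(RED = "active", YELLOW = "active", GREEN = "HP1", BLUE = "PcG",
    BLACK = "black",
    active = "active", HP1 = "HP1", PcG = "PcG", black = "black")
}

#' The merged four-state alphabet
#' @export
chromatin_states <- function() c("active", "HP1", "PcG", "black")

#' Load an epigenomic annotation and assign per-monomer states
#'
#' Reads a BED-like file (tab-separated: chrom, start, end, state; 0-based
#' half-open coordinates), merges raw labels via `merge_map`, and assigns
#' one state to each `nu`-bp monomer of the requested region by majority
#' base-pair overlap.  Monomers not covered by any interval get
#' `default_state` (with a warning).
#'
#' @param path BED file path.
#' @param region numeric `c(start, end)` in bp (0-based half-open).
#' @param nu bp per monomer; the region length must be a multiple.
#' @param chrom chromosome name to use (default: the file's first).
#' @param merge_map named vector mapping raw labels to states.
#' @param default_state state for uncovered monomers.
#' @return character vector of per-monomer states (length
#'   `(end - start) / nu`).
#' @export
load_epigenome <- function(path, region, nu, chrom = NULL,
                           merge_map = default_state_merge(),
                           default_state = "black") {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "state"))
  if (is.null(chrom)) chrom <- bed$chrom[1]
  bed <- bed[bed$chrom == chrom, , drop = FALSE]
  if (!nrow(bed)) stop("no intervals for chromosome ", chrom)
  if (any(bed$start >= bed$end)) stop("intervals must have start < end")
  unknown <- setdiff(unique(bed$state), names(merge_map))
  if (length(unknown))
    stop("unknown state label(s): ", paste(unknown, collapse = ", "))
  bed$state <- unname(merge_map[bed$state])
  n_mono <- (region[2] - region[1]) / nu
  if (abs(n_mono - round(n_mono)) > 1e-9)
    stop("region length must be a multiple of nu")
  n_mono <- as.integer(round(n_mono))
  states <- sort(unique(c(bed$state, default_state)))
  overlap <- matrix(0, n_mono, length(states), dimnames = list(NULL, states))
  for (r in seq_len(nrow(bed))) {
    lo <- max(bed$start[r], region[1]); hi <- min(bed$end[r], region[2])
    if (lo >= hi) next
    b_lo <- floor((lo - region[1]) / nu) + 1
    b_hi <- ceiling((hi - region[1]) / nu)
    for (bin in b_lo:b_hi) {
      bin_lo <- region[1] + (bin - 1) * nu
      ov <- min(hi, bin_lo + nu) - max(lo, bin_lo)
      overlap[bin, bed$state[r]] <- overlap[bin, bed$state[r]] + ov
    }
  }
  covered <- rowSums(overlap) > 0
  if (any(!covered))
    warning(sum(!covered), " monomer(s) uncovered; assigned '",
            default_state, "'")
  out <- rep(default_state, n_mono)
  out[covered] <- states[max.col(overlap[covered, , drop = FALSE],
                                 ties.method = "first")]
  out
}

#' Generate a synthetic block-copolymer epigenome
#'
#' Emulates the block-domain structure of embryonic fly chromatin
#' annotations: alternating-state blocks with geometrically distributed
#' lengths (mean `mean_domain_len` monomers) and block states drawn from
#' `state_freqs`, renormalised to exclude the previous block's state so
#' consecutive blocks always differ.  Deterministic per seed.  For strongly
#' skewed frequencies the realised state frequencies deviate slightly from
#' the targets (the no-repeat constraint biases the stationary
#' distribution); for the default near-uniform frequencies they match.
#'
#' @param n_monomers number of monomers to cover.
#' @param mean_domain_len mean block length in monomers.
#' @param state_freqs named numeric vector of target state frequencies
#'   (must sum to 1).
#' @param seed RNG seed.
#' @param nu bp per monomer (coordinates of the annotation).
#' @param chrom chromosome name.
#' @return data.frame of class `epigenome_annotation` with columns `chrom`,
#'   `start`, `end`, `state` (0-based half-open, block-aligned to `nu`);
#'   attribute `monomer_states` holds the per-monomer truth.
#' @export
synthetic_epigenome <- function(n_monomers, mean_domain_len = 10,
                                state_freqs = c(active = 0.3, HP1 = 0.1,
                                                PcG = 0.1, black = 0.5),
                                seed = 1L, nu = 10000, chrom = "chrSyn") {
  stopifnot(n_monomers >= 1, mean_domain_len >= 1)
  if (abs(sum(state_freqs) - 1) > 1e-8) stop("state_freqs must sum to 1")
  if (any(state_freqs < 0) || sum(state_freqs > 0) < 1)
    stop("degenerate state_freqs")
  set.seed(seed)
  labels <- names(state_freqs)
  single <- sum(state_freqs > 0) == 1
  blocks_state <- character(0); blocks_len <- integer(0)
  total <- 0L; prev <- NA_character_
  while (total < n_monomers) {
    if (single) {
      st <- labels[state_freqs > 0]
      len <- n_monomers
    } else {
      f <- state_freqs
      if (!is.na(prev)) f[prev] <- 0
      st <- sample(labels, 1, prob = f)
      len <- 1L + stats::rgeom(1, prob = 1 / mean_domain_len)
    }
    len <- min(len, n_monomers - total)
    blocks_state <- c(blocks_state, st)
    blocks_len <- c(blocks_len, len)
    total <- total + len
    prev <- st
  }
  ends <- cumsum(blocks_len)
  starts <- c(0L, ends[-length(ends)])
  ann <- data.frame(chrom = chrom, start = starts * nu, end = ends * nu,
                    state = blocks_state, stringsAsFactors = FALSE)
  class(ann) <- c("epigenome_annotation", "data.frame")
  attr(ann, "monomer_states") <- rep(blocks_state, blocks_len)
  attr(ann, "nu") <- nu
  ann
}

#' Write an annotation as a 4-column BED file
#'
#' @param ann an annotation data.frame (`chrom`, `start`, `end`, `state`).
#' @param path file path.
#' @export
write_epigenome_bed <- function(ann, path) {
  utils::write.table(ann[, c("chrom", "start", "end", "state")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
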
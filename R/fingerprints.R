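# Radius-2 circular (Morgan/ECFP-style) fingerprints, computed on the
# heavy-atom graph with implicit-hydrogen-aware atom invariants. The
# implementation keeps the map from every set bit back to the atom
# environments that produced it, which is what makes the downstream
# fingerprint-bit fragment analysis possible.

.HASH_MOD <- 2147483647  # 2^31 - 1, prime

# exact (a*b) %% m in double arithmetic for a, b < 2^31
.mulmod <- function(a, b, m = .HASH_MOD) {
  hi <- b %/% 65536
  lo <- b %% 65536
  (((a * hi) %% m) * 65536 + a * lo) %% m
}

# deterministic polynomial hash of a non-negative integer vector
.hash_ints <- function(v) {
  h <- 2166136261 %% .HASH_MOD
  for (x in v) {
    h <- (.mulmod(h, 16777619) + x + 1) %% .HASH_MOD
  }
  h
}

# initial atom invariants: element, heavy degree, total bond order, formal
# charge, implicit H count, ring membership
.initial_invariants <- function(g) {
  z <- .atomic_number[g$elem]
  z[is.na(z)] <- 0
  vapply(seq_len(g$n), function(a) {
    .hash_ints(c(z[a], g$degree[a], g$bondsum[a], g$charge[a] + 8,
                 g$nH[a], as.integer(g$ring_atom[a])))
  }, numeric(1))
}

# Morgan environments for one molecular graph. Returns a data.frame with
# one row per distinct environment identifier: id, atom (root of the first
# occurrence), radius.
.morgan_environments <- function(g, radius = 2) {
  inv <- .initial_invariants(g)
  envs <- data.frame(id = inv, atom = seq_len(g$n),
                     radius = 0L)
  if (radius > 0 && g$n > 1) {
    # bond order lookup per adjacency
    border <- vector("list", g$n)
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1]; j <- g$bonds[b, 2]; o <- g$bonds[b, 3]
      border[[i]] <- c(border[[i]], stats::setNames(o, j))
      border[[j]] <- c(border[[j]], stats::setNames(o, i))
    }
    for (r in seq_len(radius)) {
      new_inv <- numeric(g$n)
      for (a in seq_len(g$n)) {
        nbrs <- g$adj[[a]]
        if (length(nbrs) == 0) {
          new_inv[a] <- .hash_ints(c(r, inv[a]))
          next
        }
        ords <- as.numeric(border[[a]][as.character(nbrs)])
        pairs <- cbind(ords, inv[nbrs])
        o <- order(pairs[, 1], pairs[, 2])
        new_inv[a] <- .hash_ints(c(r, inv[a], t(pairs[o, , drop = FALSE])))
      }
      inv <- new_inv
      envs <- rbind(envs, data.frame(id = inv, atom = seq_len(g$n),
                                     radius = as.integer(r)))
    }
  }
  envs[!duplicated(envs$id), , drop = FALSE]
}

#' Compute radius-2 circular fingerprints
#'
#' Hashed binary fingerprints over circular atom environments of radius 0 to
#' `radius`, folded to `nbits` bits. Hydrogens enter only through implicit H
#' counts, so isotope-substituted molecules with the same heavy-atom graph
#' give identical bits. The returned matrix carries an environment map (one
#' entry per molecule) used by [bit_to_fragments()].
#'
#' @param records A `flavor_records` data.frame, or a character vector of
#'   valid SMILES.
#' @param radius Maximum environment radius in bonds (default 2,
#'   i.e. ECFP4-equivalent).
#' @param nbits Folded fingerprint length (default 2048).
#' @return A `feature_matrix` with `representation = "fingerprint"` and 0/1
#'   values; attribute `bit_info` maps each molecule's set bits to
#'   `(atom, radius)` environments.
#' @export
compute_fingerprints <- function(records, radius = 2, nbits = 2048) {
  smiles <- if (is.data.frame(records)) records$smiles else as.character(records)
  sdf <- parse_molecules(smiles)
  m <- matrix(0L, nrow = length(smiles), ncol = nbits,
              dimnames = list(NULL, sprintf("bit_%04d", seq_len(nbits) - 1)))
  bit_info <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    g <- mol_graph(sdf[[k]])
    envs <- .morgan_environments(g, radius)
    bits <- as.integer(envs$id %% nbits)
    m[k, bits + 1L] <- 1L
    bit_info[[k]] <- data.frame(bit = bits, atom = envs$atom,
                                radius = envs$radius)
  }
  fm <- feature_matrix(m, representation = "fingerprint")
  attr(fm, "bit_info") <- bit_info
  attr(fm, "radius") <- radius
  fm
}

# build a V2000 molblock for an environment fragment; attachment points are
# dummy "*" atoms on bonds that leave the environment
.fragment_molblock <- function(g, atoms, bonds_in, attach) {
  elems <- g$elem[atoms]
  idx <- stats::setNames(seq_along(atoms), atoms)
  blines <- character(0)
  if (nrow(bonds_in)) {
    blines <- sprintf("%3d%3d%3d  0  0  0  0",
                      idx[as.character(bonds_in[, 1])],
                      idx[as.character(bonds_in[, 2])],
                      bonds_in[, 3])
  }
  star_start <- length(elems)
  if (nrow(attach)) {
    for (s in seq_len(nrow(attach))) {
      elems <- c(elems, "*")
      blines <- c(blines,
                  sprintf("%3d%3d%3d  0  0  0  0",
                          idx[as.character(attach[s, 1])],
                          star_start + s, attach[s, 2]))
    }
  }
  alines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    elems)
  paste(c("frag", "  flavorcast", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(elems), length(blines)),
          alines, blines, "M  END", "$$$$"), collapse = "\n")
}

# SMILES (with * attachment points) of the environment rooted at `root`
.environment_fragment <- function(g, root, radius) {
  atoms <- root
  frontier <- root
  for (r in seq_len(radius)) {
    if (radius == 0) break
    frontier <- setdiff(unique(unlist(g$adj[frontier])), atoms)
    atoms <- c(atoms, frontier)
    if (!length(frontier)) break
  }
  atoms <- sort(atoms)
  inside <- g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms
  bonds_in <- g$bonds[inside, , drop = FALSE]
  # bonds crossing the boundary -> one * per crossing, attached inside
  crossing <- xor(g$bonds[, 1] %in% atoms, g$bonds[, 2] %in% atoms)
  attach <- matrix(integer(0), ncol = 2)
  if (any(crossing)) {
    cb <- g$bonds[crossing, , drop = FALSE]
    in_atom <- ifelse(cb[, 1] %in% atoms, cb[, 1], cb[, 2])
    attach <- cbind(in_atom, cb[, 3])
  }
  mb <- .fragment_molblock(g, atoms, bonds_in, attach)
  smi <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "SMI", mb)),
    error = function(e) "")
  smi <- sub("[\t\n ].*$", "", smi)
  if (!nzchar(smi)) NA_character_ else smi
}

#' Map a fingerprint bit back to molecular fragments
#'
#' For every molecule in `records` that sets `bit`, extracts the circular
#' atom environment(s) hashing to that bit as fragment structures (SMILES
#' with `*` marking attachment points), de-duplicated across molecules.
#'
#' @param records A `flavor_records` data.frame or character vector of
#'   SMILES.
#' @param bit Bit index in `0:(nbits-1)`.
#' @param nbits Folded fingerprint length used at featurization time.
#' @param radius Environment radius used at featurization time.
#' @return Character vector of unique fragment SMILES (possibly empty, with
#'   a warning, if no molecule sets the bit).
#' @export
bit_to_fragments <- function(records, bit, nbits = 2048, radius = 2) {
  stopifnot(bit >= 0, bit < nbits)
  smiles <- if (is.data.frame(records)) records$smiles else as.character(records)
  fm <- compute_fingerprints(smiles, radius = radius, nbits = nbits)
  info <- attr(fm, "bit_info")
  sdf <- parse_molecules(smiles)
  frags <- character(0)
  for (k in seq_along(smiles)) {
    hits <- info[[k]][info[[k]]$bit == bit, , drop = FALSE]
    if (!nrow(hits)) next
    g <- mol_graph(sdf[[k]])
    for (h in seq_len(nrow(hits))) {
      fr <- .environment_fragment(g, hits$atom[h], hits$radius[h])
      if (!is.na(fr)) frags <- c(frags, fr)
    }
  }
  if (!length(frags)) {
    warning("bit ", bit, " is never set in the supplied records")
    return(character(0))
  }
  unique(frags)
}
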
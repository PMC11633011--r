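# Low-level chemistry helpers shared by curation, featurization and prediction.
# All structure handling goes through OpenBabel (via ChemmineR/ChemmineOB); the
# molecular graph extracted here (atoms, bonds, implicit hydrogens, ring
# membership) feeds the descriptor and fingerprint engines.

# canonical 7-category order used everywhere in the package
FLAVOR_CATEGORIES <- c("bitter", "floral", "fruity", "off_flavor",
                       "nutty", "sour", "sweet")

#' Canonical flavor categories
#'
#' Returns the seven flavor categories in the canonical order used for all
#' label vectors, matrices and reports: bitter, floral, fruity, off_flavor,
#' nutty, sour, sweet.
#'
#' @return Character vector of length 7.
#' @export
flavor_categories <- function() FLAVOR_CATEGORIES

#' Canonicalize isomeric SMILES
#'
#' Converts SMILES strings to OpenBabel canonical isomeric SMILES.
#' Stereochemistry and isotope labels are preserved; invalid strings yield
#' `NA` rather than an error, so callers can log and drop them.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", trimws(s))),
      error = function(e) ""
    )
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Parse SMILES into an SDF container
#'
#' Thin wrapper over [ChemmineR::smiles2sdf()] that assigns stable ids and
#' refuses silently-invalid entries (callers are expected to validate with
#' [canonicalize_smiles()] first).
#'
#' @param smiles Character vector of valid SMILES.
#' @return An [ChemmineR::SDFset-class] object of the same length.
#' @export
parse_molecules <- function(smiles) {
  stopifnot(length(smiles) > 0)
  ids <- sprintf("CMP%06d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  if (length(sdf) != length(smiles)) {
    stop("SMILES parsing dropped molecules; validate inputs with canonicalize_smiles() first")
  }
  sdf
}

# number of disconnected fragments in a SMILES = dot-separated components
smiles_fragment_count <- function(smiles) {
  lengths(strsplit(smiles, ".", fixed = TRUE))
}

# default valence used to infer implicit hydrogen counts (organic subset);
# for S and P the smallest standard valence >= bond order sum is used
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, As = 3, Se = 2, Br = 1, I = 1)
.multi_valence <- list(S = c(2, 4, 6), P = c(3, 5), N = c(3, 5), As = c(3, 5),
                       Se = c(2, 4, 6))

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                    S = 16, Cl = 17, As = 33, Se = 34, Br = 35, I = 53)

# old-style MOL charge codes: 1..7 -> +3,+2,+1,radical,-1,-2,-3
.mol_charge <- function(code) {
  ifelse(code %in% 1:3, 4 - code, ifelse(code %in% 5:7, 4 - code - 8, 0L))
}

#' Extract a heavy-atom molecular graph from one SDF molecule
#'
#' Produces the annotated graph used by the descriptor and fingerprint
#' engines: element symbols, formal charges, bond list with orders, heavy
#' degree, implicit hydrogen counts, and ring-bond/ring-atom flags (ring
#' bonds are the non-bridge edges of the graph).
#'
#' @param sdf A single `SDF` object (one element of an `SDFset`).
#' @return A list with components `elem`, `charge`, `bonds` (matrix with
#'   columns i, j, order), `degree`, `nH`, `ring_bond`, `ring_atom`, `adj`
#'   (adjacency list), `n`.
#' @export
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  charge <- if ("C6" %in% colnames(ab)) .mol_charge(ab[, "C6"]) else integer(n)
  charge <- as.integer(charge)

  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
    bonds[, "order"][bonds[, "order"] == 4L] <- 1L  # aromatic code, rare here
  }

  # fold explicit hydrogens (incl. D/T written as [2H]) into the heavy-atom
  # graph, so isotope-labelled inputs give the same graph as plain ones
  explicit_h <- integer(n)
  if (any(elem == "H")) {
    h_atoms <- which(elem == "H")
    if (nrow(bonds)) {
      for (b in seq_len(nrow(bonds))) {
        i <- bonds[b, 1]; j <- bonds[b, 2]
        if (elem[i] == "H" && elem[j] != "H") explicit_h[j] <- explicit_h[j] + 1L
        if (elem[j] == "H" && elem[i] != "H") explicit_h[i] <- explicit_h[i] + 1L
      }
      keep_bond <- !(bonds[, 1] %in% h_atoms | bonds[, 2] %in% h_atoms)
      bonds <- bonds[keep_bond, , drop = FALSE]
    }
    keep <- setdiff(seq_len(n), h_atoms)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    elem <- elem[keep]; charge <- charge[keep]
    explicit_h <- explicit_h[keep]
    if (nrow(bonds)) {
      bonds[, 1] <- remap[bonds[, 1]]
      bonds[, 2] <- remap[bonds[, 2]]
    }
    n <- length(elem)
  }

  degree <- integer(n)
  bondsum <- integer(n)
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]; o <- bonds[b, 3]
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      bondsum[i] <- bondsum[i] + o; bondsum[j] <- bondsum[j] + o
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }

  nH <- integer(n)
  for (a in seq_len(n)) {
    e <- elem[a]
    occ <- bondsum[a] + explicit_h[a]  # valence occupied by all neighbours
    v <- if (e %in% names(.multi_valence)) {
      cand <- .multi_valence[[e]]
      cand <- cand[cand >= occ]
      if (length(cand)) min(cand) else occ
    } else if (e %in% names(.default_valence)) {
      .default_valence[[e]]
    } else {
      occ  # metals etc: no implicit H
    }
    nH[a] <- max(0L, as.integer(v + charge[a] - occ)) + explicit_h[a]
  }

  ring_bond <- .ring_bonds(n, bonds)
  ring_atom <- logical(n)
  if (any(ring_bond)) {
    rb <- bonds[ring_bond, , drop = FALSE]
    ring_atom[unique(c(rb[, 1], rb[, 2]))] <- TRUE
  }

  list(elem = elem, charge = charge, bonds = bonds, degree = degree,
       bondsum = bondsum, nH = nH, ring_bond = ring_bond,
       ring_atom = ring_atom, adj = adj, n = n)
}

# ring bonds = edges that are not bridges (iterative DFS bridge finding)
.ring_bonds <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  # adjacency with edge ids
  nbr <- vector("list", n)
  for (b in seq_len(m)) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    nbr[[i]] <- rbind(nbr[[i]], c(j, b))
    nbr[[j]] <- rbind(nbr[[j]], c(i, b))
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  for (start in seq_len(n)) {
    if (disc[start] != 0L) next
    # stack rows: node, parent-edge, neighbor cursor
    stack <- list(c(start, 0L, 0L))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      u <- top[1]; pe <- top[2]; cur <- top[3]
      if (cur == 0L) {
        timer <- timer + 1L
        disc[u] <- low[u] <- timer
      }
      nb <- nbr[[u]]
      advanced <- FALSE
      while (cur < NROW(nb)) {
        cur <- cur + 1L
        v <- nb[cur, 1]; eid <- nb[cur, 2]
        if (eid == pe) next
        if (disc[v] == 0L) {
          stack[[length(stack)]][3] <- cur
          stack[[length(stack) + 1]] <- c(v, eid, 0L)
          advanced <- TRUE
          break
        } else {
          low[u] <- min(low[u], disc[v])
        }
      }
      if (!advanced) {
        stack[[length(stack)]] <- NULL
        if (pe != 0L) {
          other <- if (bonds[pe, 1] == u) bonds[pe, 2] else bonds[pe, 1]
          low[other] <- min(low[other], low[u])
          if (low[u] > disc[other]) is_bridge[pe] <- TRUE
        }
      } else {
        next
      }
    }
  }
  !is_bridge
}

# all-pairs topological distances by BFS (small molecules)
.topo_dist <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    queue <- s; D[s, s] <- 0
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in g$adj[[u]]) {
        if (is.infinite(D[s, v])) {
          D[s, v] <- D[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  D
}

#' Count heavy atoms in molecules
#'
#' @param smiles Character vector of valid SMILES.
#' @return Integer vector of heavy (non-hydrogen) atom counts.
#' @export
heavy_atom_count <- function(smiles) {
  sdf <- parse_molecules(smiles)
  vapply(seq_along(sdf), function(k) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    sum(sub("_.*$", "", rownames(ab)) != "H")
  }, integer(1))
}

# SMARTS match counts over an SDFset (stderr noise from OpenBabel suppressed
# where possible; matching itself is exact)
smarts_hits <- function(sdf, smarts) {
  out <- ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE)
  as.integer(out) > 0L
}
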
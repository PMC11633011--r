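# 2-D physicochemical descriptor engine (~107 features per molecule).
#
# Families: baseline OpenBabel properties (MolWt, MolLogP, MolMR, TPSA,
# H-bond counts); composition, bond and ring counts; Kier-Hall
# electrotopological state (E-state) indices; chi connectivity and kappa
# shape indices; classic topological indices (Wiener, Zagreb, Balaban J);
# Gasteiger PEOE partial charges; a Labute-style approximate van der Waals
# surface area and the binned VSA families (PEOE_VSA, SMR_VSA, EState_VSA,
# VSA_EState). All graph-derived quantities use the heavy-atom graph with
# implicit hydrogens from mol_graph().

.vdw_radius <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, As = 1.85,
                 Se = 1.90, Br = 1.85, I = 1.98)
.cov_radius <- c(H = 0.31, B = 0.84, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
                 Si = 1.11, P = 1.06, S = 1.02, Cl = 0.99, As = 1.19,
                 Se = 1.17, Br = 1.14, I = 1.33)
.valence_e <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                S = 6, Cl = 7, As = 5, Se = 6, Br = 7, I = 7)
.pqn <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3,
          Cl = 3, As = 4, Se = 4, Br = 4, I = 5)
# element-level atomic refractivity contributions (classic values)
.atomic_mr <- c(H = 1.10, B = 3.00, C = 2.42, N = 2.74, O = 1.64, F = 1.00,
                Si = 3.50, P = 3.40, S = 7.69, Cl = 5.97, As = 6.00,
                Se = 9.00, Br = 8.87, I = 13.90)

# Gasteiger PEOE electronegativity parameters (a, b, c) by element and
# hybridization class
.peoe_params <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S.sp3  = c(10.14, 9.13, 1.38),
  S.sp2  = c(10.88, 9.48, 1.33),
  P.sp3  = c(8.90, 8.24, 0.96)
)

# VSA bin boundaries (standard published binning schemes)
.peoe_vsa_bins <- c(-0.30, -0.25, -0.20, -0.15, -0.10, -0.05, 0,
                    0.05, 0.10, 0.15, 0.20, 0.25, 0.30)
.smr_vsa_bins <- c(1.29, 1.82, 2.24, 2.45, 2.75, 3.05, 3.63, 3.80, 4.00)
.estate_vsa_bins <- c(-0.390, 0.290, 0.717, 1.165, 1.540, 1.807, 2.050,
                      4.690, 9.170, 15.000)
.vsa_estate_bins <- c(4.78, 5.00, 5.41, 5.74, 6.00, 6.07, 6.45, 7.00, 11.00)

.bin_sums <- function(values, weights, breaks) {
  idx <- findInterval(values, breaks) + 1L
  out <- numeric(length(breaks) + 1L)
  for (k in seq_along(values)) out[idx[k]] <- out[idx[k]] + weights[k]
  out
}

# hybridization class per heavy atom from incident bond orders
.hybridization <- function(g) {
  hyb <- rep("sp3", g$n)
  if (nrow(g$bonds)) {
    for (a in seq_len(g$n)) {
      orders <- c(g$bonds[g$bonds[, 1] == a | g$bonds[, 2] == a, "order"])
      if (any(orders == 3) || sum(orders == 2) >= 2) hyb[a] <- "sp"
      else if (any(orders == 2)) hyb[a] <- "sp2"
    }
  }
  hyb
}

# Gasteiger PEOE partial charges; implicit hydrogens are expanded to
# pseudo-atoms so heavy-atom charges absorb the full H inductive effect
.gasteiger_charges <- function(g, n_iter = 6) {
  hyb <- .hybridization(g)
  key <- ifelse(g$elem %in% c("H", "F", "Cl", "Br", "I"), g$elem,
                paste(g$elem, hyb, sep = "."))
  params <- lapply(key, function(k) {
    p <- .peoe_params[[k]]
    if (is.null(p)) p <- .peoe_params[["C.sp3"]]
    p
  })
  # append implicit H pseudo-atoms
  h_parent <- rep(seq_len(g$n), g$nH)
  n_all <- g$n + length(h_parent)
  a <- vapply(params, `[`, numeric(1), 1)
  b <- vapply(params, `[`, numeric(1), 2)
  cc <- vapply(params, `[`, numeric(1), 3)
  if (length(h_parent)) {
    hp <- .peoe_params[["H"]]
    a <- c(a, rep(hp[1], length(h_parent)))
    b <- c(b, rep(hp[2], length(h_parent)))
    cc <- c(cc, rep(hp[3], length(h_parent)))
  }
  edges <- rbind(g$bonds[, 1:2, drop = FALSE],
                 if (length(h_parent)) cbind(h_parent, g$n + seq_along(h_parent)))
  q <- c(as.numeric(g$charge), numeric(length(h_parent)))
  chi_plus <- a + b + cc          # cation electronegativity at q = +1
  chi_plus[a == .peoe_params[["H"]][1] & b == .peoe_params[["H"]][2]] <- 20.02
  for (t in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    damp <- 0.5^t
    dq <- numeric(n_all)
    if (NROW(edges)) {
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (chi[i] == chi[j]) next
        if (chi[j] > chi[i]) {
          d <- (chi[j] - chi[i]) / chi_plus[i] * damp
          dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
        } else {
          d <- (chi[i] - chi[j]) / chi_plus[j] * damp
          dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
        }
      }
    }
    q <- q + dq
  }
  # fold H charges back onto parents for heavy-atom reporting
  qh <- q[seq_len(g$n)]
  if (length(h_parent)) {
    extra <- tapply(q[g$n + seq_along(h_parent)], h_parent, sum)
    qh[as.integer(names(extra))] <- qh[as.integer(names(extra))] + extra
  }
  list(heavy = q[seq_len(g$n)], with_h = qh)
}

# Kier-Hall E-state indices per heavy atom
.estate_indices <- function(g, D) {
  zv <- .valence_e[g$elem]; zv[is.na(zv)] <- 4
  pq <- .pqn[g$elem]; pq[is.na(pq)] <- 3
  delta <- pmax(g$degree, 1)
  delta_v <- pmax(zv - g$nH, 1)
  I <- ((2 / pq)^2 * delta_v + 1) / delta
  S <- I
  if (g$n > 1) {
    for (i in seq_len(g$n)) {
      d <- D[i, -i]
      S[i] <- I[i] + sum((I[i] - I[-i]) / (d + 1)^2)
    }
  }
  S
}

# approximate per-atom van der Waals surface areas (sphere areas minus
# spherical caps cut off by bonded neighbours, implicit H included)
.atom_vsa <- function(g) {
  r <- .vdw_radius[g$elem]; r[is.na(r)] <- 1.7
  rc <- .cov_radius[g$elem]; rc[is.na(rc)] <- 0.77
  area <- 4 * pi * r^2
  cap <- function(Ri, Rj, d) {
    h <- Ri - (d^2 + Ri^2 - Rj^2) / (2 * d)
    2 * pi * Ri * min(max(h, 0), 2 * Ri)
  }
  if (nrow(g$bonds)) {
    for (e in seq_len(nrow(g$bonds))) {
      i <- g$bonds[e, 1]; j <- g$bonds[e, 2]; o <- g$bonds[e, 3]
      d <- (rc[i] + rc[j]) * (1 - 0.08 * (o - 1))
      area[i] <- area[i] - cap(r[i], r[j], d)
      area[j] <- area[j] - cap(r[j], r[i], d)
    }
  }
  for (a in seq_len(g$n)) {
    if (g$nH[a] > 0) {
      d <- rc[a] + .cov_radius[["H"]]
      area[a] <- area[a] - g$nH[a] * cap(r[a], .vdw_radius[["H"]], d)
    }
  }
  pmax(area, 0)
}

# simple paths of a given edge length (each undirected path counted once);
# returns list of atom-index paths
.simple_paths <- function(g, len) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) == len + 1) {
      if (path[1] < path[length(path)] ||
          (path[1] == path[length(path)])) {
        paths[[length(paths) + 1]] <<- path
      }
      return(invisible())
    }
    for (v in g$adj[[last]]) {
      if (!(v %in% path)) walk(c(path, v))
    }
  }
  for (s in seq_len(g$n)) walk(s)
  paths
}

# all descriptor values for one molecule graph
.graph_descriptors <- function(g) {
  out <- c()
  n <- g$n
  m <- nrow(g$bonds)

  elems <- g$elem
  cnt <- function(e) sum(elems == e)
  n_hal <- cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")
  hyb <- .hybridization(g)
  csp3 <- sum(elems == "C" & hyb == "sp3")
  out <- c(out,
           HeavyAtomCount = n, nC = cnt("C"), nN = cnt("N"), nO = cnt("O"),
           nS = cnt("S"), nP = cnt("P"), nF = cnt("F"), nCl = cnt("Cl"),
           nBr = cnt("Br"), nI = cnt("I"), NumHalogens = n_hal,
           NumHeteroatoms = sum(!elems %in% c("C", "H")),
           TotalNumH = sum(g$nH),
           FractionCSP3 = if (cnt("C") > 0) csp3 / cnt("C") else 0)

  orders <- if (m) g$bonds[, "order"] else integer(0)
  rot <- 0L
  if (m) {
    for (e in seq_len(m)) {
      i <- g$bonds[e, 1]; j <- g$bonds[e, 2]
      if (orders[e] == 1 && !g$ring_bond[e] &&
          g$degree[i] > 1 && g$degree[j] > 1) rot <- rot + 1L
    }
  }
  out <- c(out,
           NumBonds = m, NumSingleBonds = sum(orders == 1),
           NumDoubleBonds = sum(orders == 2),
           NumTripleBonds = sum(orders == 3),
           NumRotatableBonds = rot, NumRingBonds = sum(g$ring_bond))

  ring_count <- m - n + 1L  # cyclomatic number (single fragment)
  out <- c(out, RingCount = max(ring_count, 0L),
           RingAtomFraction = mean(g$ring_atom))

  D <- .topo_dist(g)
  S <- .estate_indices(g, D)
  hal <- elems %in% c("F", "Cl", "Br", "I")
  out <- c(out,
           MinEStateIndex = min(S), MaxEStateIndex = max(S),
           MeanEStateIndex = mean(S), SumEStateIndex = sum(S),
           MinAbsEStateIndex = min(abs(S)), MaxAbsEStateIndex = max(abs(S)),
           EState_SumC = sum(S[elems == "C"]),
           EState_SumN = sum(S[elems == "N"]),
           EState_SumO = sum(S[elems == "O"]),
           EState_SumS = sum(S[elems == "S"]),
           EState_SumHal = sum(S[hal]))

  zv <- .valence_e[elems]; zv[is.na(zv)] <- 4
  delta <- pmax(g$degree, 1)
  delta_v <- pmax(zv - g$nH, 1)
  p2 <- .simple_paths(g, 2)
  p3 <- .simple_paths(g, 3)
  chi_path <- function(paths, d) {
    if (!length(paths)) return(0)
    sum(vapply(paths, function(p) 1 / sqrt(prod(d[p])), numeric(1)))
  }
  chi1 <- if (m) sum(1 / sqrt(delta[g$bonds[, 1]] * delta[g$bonds[, 2]])) else 0
  chi1v <- if (m) sum(1 / sqrt(delta_v[g$bonds[, 1]] * delta_v[g$bonds[, 2]])) else 0
  out <- c(out,
           Chi0 = sum(1 / sqrt(delta)), Chi1 = chi1,
           Chi2 = chi_path(p2, delta), Chi3 = chi_path(p3, delta),
           Chi0v = sum(1 / sqrt(delta_v)), Chi1v = chi1v,
           Chi2v = chi_path(p2, delta_v), Chi3v = chi_path(p3, delta_v))

  rc <- .cov_radius[elems]; rc[is.na(rc)] <- 0.77
  alpha <- sum(rc / 0.77 - 1)
  P1 <- m; P2 <- length(p2); P3 <- length(p3)
  A <- n + alpha
  kappa1 <- if (P1 + alpha > 0) A * (A - 1)^2 / (P1 + alpha)^2 else 0
  kappa2 <- if (P2 + alpha > 0 && n > 2) (A - 1) * (A - 2)^2 / (P2 + alpha)^2 else 0
  kappa3 <- if (P3 + alpha > 0 && n > 3) {
    if (n %% 2 == 1) (A - 1) * (A - 3)^2 / (P3 + alpha)^2
    else (A - 3) * (A - 2)^2 / (P3 + alpha)^2
  } else 0
  out <- c(out, Kappa1 = kappa1, Kappa2 = kappa2, Kappa3 = kappa3,
           HallKierAlpha = alpha)

  finite_D <- D[is.finite(D)]
  wiener <- sum(finite_D) / 2
  zag1 <- sum(delta^2)
  zag2 <- if (m) sum(delta[g$bonds[, 1]] * delta[g$bonds[, 2]]) else 0
  balaban <- 0
  if (m > 0 && n > 2) {
    s <- rowSums(D)
    gamma <- m - n + 1
    balaban <- m / (gamma + 1) *
      sum(1 / sqrt(s[g$bonds[, 1]] * s[g$bonds[, 2]]))
  }
  out <- c(out, WienerIndex = wiener, ZagrebM1 = zag1, ZagrebM2 = zag2,
           BalabanJ = balaban)

  vsa <- .atom_vsa(g)
  out <- c(out, LabuteASA = sum(vsa))

  q <- .gasteiger_charges(g)$with_h
  out <- c(out,
           MaxPartialCharge = max(q), MinPartialCharge = min(q),
           MaxAbsPartialCharge = max(abs(q)),
           MinAbsPartialCharge = min(abs(q)))

  mr <- .atomic_mr[elems]; mr[is.na(mr)] <- 2.42
  peoe_vsa <- .bin_sums(q, vsa, .peoe_vsa_bins)
  smr_vsa <- .bin_sums(mr, vsa, .smr_vsa_bins)
  estate_vsa <- .bin_sums(S, vsa, .estate_vsa_bins)
  vsa_estate <- .bin_sums(vsa, S, .vsa_estate_bins)
  names(peoe_vsa) <- sprintf("PEOE_VSA%d", seq_along(peoe_vsa))
  names(smr_vsa) <- sprintf("SMR_VSA%d", seq_along(smr_vsa))
  names(estate_vsa) <- sprintf("EState_VSA%d", seq_along(estate_vsa))
  names(vsa_estate) <- sprintf("VSA_EState%d", seq_along(vsa_estate))

  c(out, peoe_vsa, smr_vsa, estate_vsa, vsa_estate)
}

#' Compute the physicochemical descriptor matrix
#'
#' One row per record, ~107 named 2-D descriptors per molecule (see the
#' module header for the families). Descriptor failures for individual
#' molecules yield missing cells (logged in the `failures` attribute) and
#' are removed later by the column-level invalid filter, so compounds are
#' never dropped here.
#'
#' @param records A `flavor_records` data.frame or character vector of valid
#'   SMILES.
#' @return A `feature_matrix` with `representation = "descriptors"`.
#' @export
compute_descriptors <- function(records) {
  smiles <- if (is.data.frame(records)) records$smiles else as.character(records)
  sdf <- parse_molecules(smiles)

  ob <- tryCatch(suppressWarnings(ChemmineR::propOB(sdf)),
                 error = function(e) NULL)
  ob_cols <- c(MolWt = "MW", MolLogP = "logP", MolMR = "MR", TPSA = "TPSA",
               NumHBA = "HBA1", NumHBALipinski = "HBA2", NumHBD = "HBD")
  ob_mat <- matrix(NA_real_, nrow = length(smiles), ncol = length(ob_cols),
                   dimnames = list(NULL, names(ob_cols)))
  if (!is.null(ob)) {
    for (k in seq_along(ob_cols)) {
      v <- ob[[ob_cols[[k]]]]
      if (!is.null(v)) ob_mat[, k] <- suppressWarnings(as.numeric(v))
    }
  }

  arom_rings <- rep(NA_real_, length(smiles))
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "count", arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(rng)) {
    rng <- as.data.frame(rng)
    if ("AROMATIC" %in% colnames(rng)) arom_rings <- as.numeric(rng$AROMATIC)
  }

  failures <- character(0)
  rows <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    rows[[k]] <- tryCatch(
      .graph_descriptors(mol_graph(sdf[[k]])),
      error = function(e) {
        failures <<- c(failures, paste0(smiles[k], ": ", conditionMessage(e)))
        NULL
      })
  }
  template <- rows[[which(!vapply(rows, is.null, logical(1)))[1]]]
  graph_mat <- t(vapply(rows, function(r) {
    if (is.null(r)) rep(NA_real_, length(template)) else r
  }, numeric(length(template))))
  colnames(graph_mat) <- names(template)

  values <- cbind(ob_mat, AromaticRingCount = arom_rings, graph_mat)
  fm <- feature_matrix(values, representation = "descriptors")
  attr(fm, "failures") <- failures
  fm
}
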
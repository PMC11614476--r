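# Ligand SMILES -> atom/bond feature graph.
#
# Parsing goes through OpenBabel (ChemmineOB/ChemmineR): an SDF conversion
# supplies the heavy-atom graph, formal charges, tetrahedral parity and
# (via a second conversion with explicit hydrogens) attached-H counts; a
# MOL2 conversion supplies OpenBabel's perceived atom types, from which
# hybridization and aromaticity are read (C.ar, C.2, ...). Ring membership
# comes from the graph itself (an edge is in a ring iff it is not a bridge).

ELEMENT_Z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Zn = 30, Se = 34,
  Br = 35, I = 53
)

# categorical vocabularies; the last level of each is the out-of-vocabulary
# bucket used for anything unseen
ligand_vocab <- function() {
  list(
    atomic_number = c(5, 6, 7, 8, 9, 14, 15, 16, 17, 35, 53, -1),
    chirality = c(0, 1, 2, -1),           # SDF parity codes + OOV
    degree = c(0, 1, 2, 3, 4, 5, 6, -1),
    formal_charge = c(-2, -1, 0, 1, 2, -99),
    attached_hydrogens = c(0, 1, 2, 3, 4, -1),
    radical_electrons = c(0, 1, 2, -1),
    hybridization = c("sp", "sp2", "sp3", "aromatic", "other"),
    is_aromatic = c(FALSE, TRUE),
    in_ring = c(FALSE, TRUE),
    bond_type = c("single", "double", "triple", "aromatic", "other"),
    bond_stereo = c(0, 1, 4, 6, -1),      # SDF wedge/hash/either codes + OOV
    is_conjugated = c(FALSE, TRUE)
  )
}

ob_convert <- function(smiles, to, opts = NULL) {
  out <- if (is.null(opts)) {
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n")))
  } else {
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n"),
                                               options = opts))
  }
  if (!nzchar(trimws(out))) {
    stop("SMILES string could not be parsed: '", smiles, "'")
  }
  out
}

# V2000 molblock reader (the SDF text comes straight from OpenBabel).
# Whitespace-tokenized atom lines: x y z symbol massdiff charge parity ...;
# fixed-width bond lines; M CHG/M RAD property lines override the old-style
# per-atom codes.
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n")[[1]]
  counts <- lines[4]
  n_at <- as.integer(substr(counts, 1, 3))
  n_bd <- as.integer(substr(counts, 4, 6))
  atoms <- data.frame(
    sym = character(n_at), chg_code = integer(n_at), parity = integer(n_at),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n_at)) {
    f <- strsplit(trimws(lines[4 + k]), "\\s+")[[1]]
    atoms$sym[k] <- f[4]
    atoms$chg_code[k] <- as.integer(f[6])
    atoms$parity[k] <- as.integer(f[7])
  }
  bonds <- matrix(0L, n_bd, 4L)
  for (k in seq_len(n_bd)) {
    ln <- lines[4 + n_at + k]
    bonds[k, ] <- c(
      as.integer(substr(ln, 1, 3)), as.integer(substr(ln, 4, 6)),
      as.integer(substr(ln, 7, 9)), as.integer(substr(ln, 10, 12))
    )
  }
  charge <- integer(n_at)
  charge[atoms$chg_code %in% 1:3] <- 4L - atoms$chg_code[atoms$chg_code %in% 1:3]
  charge[atoms$chg_code %in% 5:7] <- -(atoms$chg_code[atoms$chg_code %in% 5:7] - 4L)
  radical <- as.integer(atoms$chg_code == 4L)
  for (ln in grep("^M  (CHG|RAD)", lines, value = TRUE)) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    npair <- as.integer(f[3])
    for (p in seq_len(npair)) {
      idx <- as.integer(f[2 + 2 * p])
      vl <- as.integer(f[3 + 2 * p])
      if (f[2] == "CHG") charge[idx] <- vl else radical[idx] <- vl
    }
  }
  list(
    sym = atoms$sym, charge = charge, radical = radical,
    parity = atoms$parity, bonds = bonds
  )
}

parse_mol2_types <- function(mol2) {
  lines <- strsplit(mol2, "\n")[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  sect <- function(start) {
    out <- character(0)
    i <- start + 1L
    while (i <= length(lines) && !startsWith(lines[i], "@<TRIPOS>")) {
      if (nzchar(trimws(lines[i]))) out <- c(out, lines[i])
      i <- i + 1L
    }
    out
  }
  atom_fields <- lapply(strsplit(trimws(sect(a0)), "\\s+"), identity)
  bond_fields <- lapply(strsplit(trimws(sect(b0)), "\\s+"), identity)
  list(
    atom_type = vapply(atom_fields, `[[`, character(1), 6L),
    bond = if (length(bond_fields)) t(vapply(
      bond_fields, function(f) f[2:4], character(3)
    )) else matrix(character(0), 0, 3)
  )
}

#' Featurize a ligand SMILES string into an atom/bond graph
#'
#' Builds the per-atom and per-bond categorical feature records that seed the
#' ligand part of the single and pair representations: atomic number,
#' tetrahedral parity, heavy-atom degree, formal charge, attached hydrogens,
#' radical electrons, hybridization, aromaticity and ring membership per
#' atom; bond type, stereochemistry code and conjugation per bond. Every
#' field has a fixed vocabulary with an out-of-vocabulary bucket. The masked
#' ligand \code{"*"} yields a graph with zero atoms.
#'
#' @param smiles a SMILES string, or \code{"*"} for an unspecified ligand.
#' @return an object of class \code{ligand_graph}: list with \code{atoms}
#'   (data.frame, one row per heavy atom), \code{bonds} (data.frame, one row
#'   per undirected bond with \code{i < j}), \code{is_masked_ligand},
#'   \code{smiles}.
#' @export
featurize_ligand <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  smiles <- trimws(smiles)
  if (identical(smiles, "*")) {
    return(structure(
      list(
        atoms = empty_atoms(), bonds = empty_bonds(),
        is_masked_ligand = TRUE, smiles = "*"
      ),
      class = "ligand_graph"
    ))
  }

  mb <- parse_molblock(ob_convert(smiles, "SDF",
                                 opts = data.frame(names = "gen2d", args = "")))
  n <- length(mb$sym)
  z <- unname(ELEMENT_Z[mb$sym])
  z[is.na(z)] <- -1
  charge <- mb$charge
  radical <- mb$radical
  parity <- mb$parity

  has_bonds <- nrow(mb$bonds) > 0
  bi <- if (has_bonds) pmin(mb$bonds[, 1], mb$bonds[, 2]) else integer(0)
  bj <- if (has_bonds) pmax(mb$bonds[, 1], mb$bonds[, 2]) else integer(0)
  border <- if (has_bonds) mb$bonds[, 3] else integer(0)
  bstereo <- if (has_bonds) mb$bonds[, 4] else integer(0)

  degree <- tabulate(c(bi, bj), nbins = n)

  # attached hydrogens: re-convert with explicit H, count H neighbours
  mbh <- parse_molblock(ob_convert(smiles, "SDF",
                                   opts = data.frame(names = c("gen2d", "h"),
                                                     args = c("", ""))))
  n_h <- integer(n)
  heavy_idx <- which(mbh$sym != "H")     # heavy atoms keep their input order
  if (nrow(mbh$bonds) > 0) {
    for (rr in seq_len(nrow(mbh$bonds))) {
      a <- mbh$bonds[rr, 1]; b <- mbh$bonds[rr, 2]
      if (mbh$sym[a] == "H" && mbh$sym[b] != "H") {
        k <- match(b, heavy_idx); n_h[k] <- n_h[k] + 1L
      } else if (mbh$sym[b] == "H" && mbh$sym[a] != "H") {
        k <- match(a, heavy_idx); n_h[k] <- n_h[k] + 1L
      }
    }
  }

  # OpenBabel atom typing via MOL2 for hybridization/aromaticity
  m2 <- parse_mol2_types(ob_convert(smiles, "MOL2"))
  atype <- m2$atom_type
  aromatic <- grepl("\\.ar$", atype) | atype %in% c("N.ar", "C.ar")
  hyb <- rep("other", n)
  hyb[grepl("\\.3$", atype)] <- "sp3"
  hyb[grepl("\\.2$", atype) | grepl("\\.(am|pl3|co2)$", atype)] <- "sp2"
  hyb[grepl("\\.1$", atype)] <- "sp"
  hyb[aromatic] <- "aromatic"
  hyb[atype %in% c("O.3", "N.3", "S.3")] <- "sp3"

  # ring membership: an edge lies on a ring iff it is not a bridge
  in_ring_atom <- rep(FALSE, n)
  in_ring_bond <- rep(FALSE, length(bi))
  if (has_bonds) {
    g <- igraph::graph_from_edgelist(cbind(bi, bj), directed = FALSE)
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_along(bi), as.integer(br))
    in_ring_bond[ring_edges] <- TRUE
    in_ring_atom[unique(c(bi[ring_edges], bj[ring_edges]))] <- TRUE
  }

  bond_aromatic <- rep(FALSE, length(bi))
  if (has_bonds && nrow(m2$bond) > 0) {
    # match MOL2 "ar" bonds back to SDF bond order (same atom indexing)
    m2i <- pmin(as.integer(m2$bond[, 1]), as.integer(m2$bond[, 2]))
    m2j <- pmax(as.integer(m2$bond[, 1]), as.integer(m2$bond[, 2]))
    ar <- m2$bond[, 3] == "ar"
    key_sdf <- paste(bi, bj); key_m2 <- paste(m2i, m2j)
    # MOL2 also marks delocalized (e.g. carboxyl) bonds "ar"; require both
    # endpoints to be aromatic atoms before calling the bond aromatic
    bond_aromatic <- (key_sdf %in% key_m2[ar]) & aromatic[bi] & aromatic[bj]
  }
  btype <- rep("other", length(bi))
  btype[border == 1] <- "single"
  btype[border == 2] <- "double"
  btype[border == 3] <- "triple"
  btype[bond_aromatic] <- "aromatic"
  conj <- bond_aromatic |
    (hyb[bi] %in% c("sp", "sp2", "aromatic") & hyb[bj] %in% c("sp", "sp2", "aromatic"))

  atoms <- data.frame(
    atomic_number = z,
    chirality = parity,
    degree = degree,
    formal_charge = charge,
    attached_hydrogens = n_h,
    radical_electrons = radical,
    hybridization = hyb,
    is_aromatic = aromatic,
    in_ring = in_ring_atom,
    stringsAsFactors = FALSE
  )
  bonds_df <- data.frame(
    atom_i = as.integer(bi), atom_j = as.integer(bj),
    bond_type = btype,
    stereochemistry = as.integer(bstereo),
    is_conjugated = conj,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      atoms = atoms, bonds = bonds_df,
      is_masked_ligand = FALSE, smiles = smiles
    ),
    class = "ligand_graph"
  )
}

empty_atoms <- function() {
  data.frame(
    atomic_number = integer(0), chirality = integer(0), degree = integer(0),
    formal_charge = integer(0), attached_hydrogens = integer(0),
    radical_electrons = integer(0), hybridization = character(0),
    is_aromatic = logical(0), in_ring = logical(0), stringsAsFactors = FALSE
  )
}
empty_bonds <- function() {
  data.frame(
    atom_i = integer(0), atom_j = integer(0), bond_type = character(0),
    stereochemistry = integer(0), is_conjugated = logical(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ligand_graph <- function(x, ...) {
  if (x$is_masked_ligand) {
    cat("<ligand_graph: masked ligand '*', 0 atoms>\n")
  } else {
    cat(sprintf(
      "<ligand_graph: '%s', %d atoms, %d bonds>\n",
      x$smiles, nrow(x$atoms), nrow(x$bonds)
    ))
  }
  invisible(x)
}

n_ligand_atoms <- function(ligand) nrow(ligand$atoms)
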
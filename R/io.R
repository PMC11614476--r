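# PDB subset input/output: C-alpha trace as ATOM records (chain A) and one
# HETATM per ligand heavy atom (chain L, residue LIG). Reading goes through
# bio3d; writing is a fixed-width formatter for exactly this subset.

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK", `-` = "UNK"
)
AA_ONE <- stats::setNames(names(AA_THREE)[1:21], AA_THREE[1:21])

element_symbol <- function(z) {
  s <- names(ELEMENT_Z)[match(z, ELEMENT_Z)]
  s[is.na(s)] <- "C"
  s
}

#' Write a complex as a PDB file
#'
#' One \code{ATOM} record per residue (atom name CA, chain A) followed by one
#' \code{HETATM} per ligand heavy atom (chain L, residue LIG), then
#' \code{TER}/\code{END}. Coordinates use the fixed \code{\%8.3f} PDB fields;
#' occupancy 1.00. Writing the same complex twice yields byte-identical
#' files.
#'
#' @param complex a [generate_toy_complex()] object, or any list with
#'   \code{sequence}, \code{coords} and \code{ligand}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(complex, path) {
  seq <- aa_seq(complex$sequence)
  n_res <- length(seq)
  coords <- as.matrix(complex$coords)
  if (any(abs(coords) >= 10000)) stop("coordinates overflow the PDB fixed-width field")
  n_lig <- nrow(coords) - n_res
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_res)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, AA_THREE[[unclass(seq)[i]]], i,
      coords[i, 1], coords[i, 2], coords[i, 3]
    ))
  }
  lines <- c(lines, sprintf("TER   %5d      %3s A%4d",
                            serial + 1L, AA_THREE[[unclass(seq)[n_res]]], n_res))
  serial <- serial + 1L
  if (n_lig > 0) {
    elems <- if (!is.null(complex$ligand) && nrow(complex$ligand$atoms) == n_lig) {
      element_symbol(complex$ligand$atoms$atomic_number)
    } else {
      rep("C", n_lig)
    }
    for (k in seq_len(n_lig)) {
      serial <- serial + 1L
      nm <- sprintf("%s%d", elems[k], k)
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s LIG L%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, substr(nm, 1, 4), 1L,
        coords[n_res + k, 1], coords[n_res + k, 2], coords[n_res + k, 3],
        elems[k]
      ))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a C-alpha + ligand structure from a PDB file
#'
#' Returns the C-alpha atoms of chain-ordered residues plus all HETATM heavy
#' atoms (waters excluded), in angstrom, 1-based residue numbering preserved.
#' When a residue lacks a C-alpha it errors, or warns and skips it under
#' \code{skip_missing_ca = TRUE}. For duplicated altlocs the first is kept.
#'
#' @param path PDB file.
#' @param skip_missing_ca warn-and-skip instead of erroring on residues with
#'   no C-alpha atom.
#' @return list with \code{coords} (tokens x 3, residues first),
#'   \code{sequence} (aa_seq), \code{n_res}, \code{resno} (original residue
#'   numbers), \code{ligand_elements}.
#' @export
read_structure <- function(path, skip_missing_ca = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty structure: no ATOM records in ", path)
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) stop("empty structure: no ATOM records in ", path)
  # first altloc wins
  prot <- prot[!duplicated(prot[, c("chain", "resno", "elety")]), , drop = FALSE]
  key <- paste(prot$chain, prot$resno)
  res_keys <- unique(key)
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno)
  missing <- setdiff(res_keys, ca_key)
  if (length(missing) > 0) {
    if (!skip_missing_ca) stop("residue(s) without a C-alpha atom: ",
                               paste(missing, collapse = ", "))
    warning("skipping ", length(missing), " residue(s) without a C-alpha atom")
  }
  ca <- ca[match(intersect(res_keys, ca_key), ca_key), , drop = FALSE]
  seq1 <- unname(AA_ONE[ca$resid])
  seq1[is.na(seq1)] <- AA_UNKNOWN
  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT")) &
              at$elesy != "H", , drop = FALSE]
  coords <- rbind(
    as.matrix(ca[, c("x", "y", "z")]),
    as.matrix(het[, c("x", "y", "z")])
  )
  rownames(coords) <- NULL
  list(
    coords = coords,
    sequence = aa_seq(seq1),
    n_res = nrow(ca),
    resno = ca$resno,
    ligand_elements = het$elesy
  )
}
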
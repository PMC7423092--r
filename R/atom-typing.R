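#' The 13 atom types
#'
#' Heavy atoms of the 20 standard amino acids are classified into 13 types
#' that group atoms by element and bond order environment; `"_bb"` marks
#' backbone types. The closed set is: `C_single`, `C_single_bb`, `C_double`,
#' `C_double_bb`, `C_intermediate`, `O_single`, `O_double`, `O_double_bb`,
#' `O_intermediate`, `N_single`, `N_single_bb`, `N_intermediate`,
#' `S_single`.
#'
#' @return Character vector of the 13 type names, in the fixed order used
#'   for deterministic tie-breaking.
#' @export
atom_types <- function() {
  c("C_double", "C_double_bb", "C_intermediate", "C_single", "C_single_bb",
    "N_intermediate", "N_single", "N_single_bb",
    "O_double", "O_double_bb", "O_intermediate", "O_single",
    "S_single")
}

standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

element_z <- function(element) {
  z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, `NA` = 11, MG = 12, P = 15, S = 16,
         CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28,
         CU = 29, ZN = 30, SE = 34, BR = 35, I = 53)
  unname(z[toupper(element)])
}

# Side-chain typing and bonded-hydrogen counts at standard pH-7 protonation
# (Arg/Lys protonated, Asp/Glu deprotonated, His neutral with the ring
# proton on ND1). Backbone atoms are handled separately in atom_typing_table.
.side_chain_def <- function() {
  L <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(atom = m[, 1], type = m[, 2], n_h = as.integer(m[, 3]))
  }
  list(
    ALA = L("CB", "C_single", 3),
    ARG = L("CB", "C_single", 2, "CG", "C_single", 2, "CD", "C_single", 2,
            "NE", "N_intermediate", 1, "CZ", "C_intermediate", 0,
            "NH1", "N_intermediate", 2, "NH2", "N_intermediate", 2),
    ASN = L("CB", "C_single", 2, "CG", "C_double", 0,
            "OD1", "O_double", 0, "ND2", "N_intermediate", 2),
    ASP = L("CB", "C_single", 2, "CG", "C_intermediate", 0,
            "OD1", "O_intermediate", 0, "OD2", "O_intermediate", 0),
    CYS = L("CB", "C_single", 2, "SG", "S_single", 1),
    GLN = L("CB", "C_single", 2, "CG", "C_single", 2, "CD", "C_double", 0,
            "OE1", "O_double", 0, "NE2", "N_intermediate", 2),
    GLU = L("CB", "C_single", 2, "CG", "C_single", 2, "CD", "C_intermediate", 0,
            "OE1", "O_intermediate", 0, "OE2", "O_intermediate", 0),
    GLY = tibble(atom = character(), type = character(), n_h = integer()),
    HIS = L("CB", "C_single", 2, "CG", "C_intermediate", 0,
            "ND1", "N_intermediate", 1, "CD2", "C_intermediate", 1,
            "CE1", "C_intermediate", 1, "NE2", "N_intermediate", 0),
    ILE = L("CB", "C_single", 1, "CG1", "C_single", 2, "CG2", "C_single", 3,
            "CD1", "C_single", 3),
    LEU = L("CB", "C_single", 2, "CG", "C_single", 1, "CD1", "C_single", 3,
            "CD2", "C_single", 3),
    LYS = L("CB", "C_single", 2, "CG", "C_single", 2, "CD", "C_single", 2,
            "CE", "C_single", 2, "NZ", "N_single", 3),
    MET = L("CB", "C_single", 2, "CG", "C_single", 2, "SD", "S_single", 0,
            "CE", "C_single", 3),
    PHE = L("CB", "C_single", 2, "CG", "C_intermediate", 0,
            "CD1", "C_intermediate", 1, "CD2", "C_intermediate", 1,
            "CE1", "C_intermediate", 1, "CE2", "C_intermediate", 1,
            "CZ", "C_intermediate", 1),
    PRO = L("CB", "C_single", 2, "CG", "C_single", 2, "CD", "C_single", 2),
    SER = L("CB", "C_single", 2, "OG", "O_single", 1),
    THR = L("CB", "C_single", 1, "OG1", "O_single", 1, "CG2", "C_single", 3),
    TRP = L("CB", "C_single", 2, "CG", "C_intermediate", 0,
            "CD1", "C_intermediate", 1, "NE1", "N_intermediate", 1,
            "CD2", "C_intermediate", 0, "CE2", "C_intermediate", 0,
            "CE3", "C_intermediate", 1, "CZ2", "C_intermediate", 1,
            "CZ3", "C_intermediate", 1, "CH2", "C_intermediate", 1),
    TYR = L("CB", "C_single", 2, "CG", "C_intermediate", 0,
            "CD1", "C_intermediate", 1, "CD2", "C_intermediate", 1,
            "CE1", "C_intermediate", 1, "CE2", "C_intermediate", 1,
            "CZ", "C_intermediate", 0, "OH", "O_single", 1),
    VAL = L("CB", "C_single", 1, "CG1", "C_single", 3, "CG2", "C_single", 3)
  )
}

#' Atom type and electron count lookup table
#'
#' One row per (residue, heavy atom) of the 20 standard amino acids:
#' the atom type, the element, the number of covalently bonded hydrogens at
#' standard protonation, and the folded electron count
#' `z_e = Z(element) + n_H` (hydrogens are not resolvable in the maps, so
#' their electrons are added to the bonded heavy atom). Backbone atoms
#' (N, CA, C, O plus terminal OXT) are included for every residue; the
#' proline backbone N carries no hydrogen and glycine's CA carries two.
#'
#' @return A tibble with columns `resname`, `atom`, `type`, `element`,
#'   `n_h`, `z_e`.
#' @export
atom_typing_table <- function() {
  cached <- .edmapr_cache$typing
  if (!is.null(cached)) return(cached)
  sc <- .side_chain_def()
  rows <- purrr::map(standard_residues(), function(rn) {
    bb <- tibble(
      atom = c("N", "CA", "C", "O", "OXT"),
      type = c("N_single_bb", "C_single_bb", "C_double_bb", "O_double_bb",
               "O_intermediate"),
      n_h = c(if (rn == "PRO") 0L else 1L, if (rn == "GLY") 2L else 1L, 0L, 0L, 0L)
    )
    bind_rows(bb, sc[[rn]]) %>% mutate(resname = rn, .before = 1)
  })
  out <- bind_rows(rows) %>%
    mutate(element = substr(.data$atom, 1, 1),
           z_e = element_z(.data$element) + .data$n_h)
  .edmapr_cache$typing <- out
  out
}

.edmapr_cache <- new.env(parent = emptyenv())

#' Classify a heavy atom into one of the 13 atom types
#'
#' @param resname Three-letter residue name (one of the 20 standard amino
#'   acids); vectorized.
#' @param atom_name Heavy-atom name per PDB convention (e.g. `"CA"`,
#'   `"OD1"`); vectorized.
#' @return Character vector of atom types; `NA` for unclassifiable atoms
#'   (non-standard residue or unknown atom name), which are excluded from
#'   density-ratio analysis but retained for the F000 estimate.
#' @examples
#' classify_atom("LEU", c("CB", "C"))
#' @export
classify_atom <- function(resname, atom_name) {
  tab <- atom_typing_table()
  key <- paste(toupper(resname), toupper(atom_name))
  tab$type[match(key, paste(tab$resname, tab$atom))]
}

#' Electron count of a heavy atom with folded hydrogens
#'
#' @inheritParams classify_atom
#' @param element Element symbol; used as fallback (element-only count, no
#'   hydrogens) for atoms outside the typing table.
#' @return Integer electron count `Z_i`; `NA` if neither the table nor the
#'   element resolves.
#' @examples
#' electron_count("ALA", "CB")  # CH3: 6 + 3
#' @export
electron_count <- function(resname, atom_name, element = NULL) {
  tab <- atom_typing_table()
  key <- paste(toupper(resname), toupper(atom_name))
  z <- tab$z_e[match(key, paste(tab$resname, tab$atom))]
  if (!is.null(element)) {
    miss <- is.na(z)
    z[miss] <- element_z(element[miss])
  }
  as.integer(z)
}
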
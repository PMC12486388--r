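# Shipped lookup tables for per-atom attributes and residue max-ASA.
# Attribute conventions: masses and van der Waals radii by element; partial
# charges follow a coarse force-field-style convention (polarised backbone,
# ionised Asp/Glu carboxylates, protonated Lys/Arg); bonded-hydrogen counts
# assume standard protonation at neutral pH; ring membership covers the
# aromatic/imidazole side chains and the proline ring.

.element_props <- data.frame(
  element = c("C", "N", "O", "S"),
  mass = c(12.011, 14.007, 15.999, 32.06),
  vdw = c(1.70, 1.55, 1.52, 1.80),
  stringsAsFactors = FALSE
)

.backbone_nh <- c(N = 1, CA = 1, C = 0, O = 0, OXT = 0)

.sidechain_nh <- list(
  ALA = c(CB = 3),
  ARG = c(CB = 2, CG = 2, CD = 2, NE = 1, CZ = 0, NH1 = 2, NH2 = 2),
  ASN = c(CB = 2, CG = 0, OD1 = 0, ND2 = 2),
  ASP = c(CB = 2, CG = 0, OD1 = 0, OD2 = 0),
  CYS = c(CB = 2, SG = 1),
  GLN = c(CB = 2, CG = 2, CD = 0, OE1 = 0, NE2 = 2),
  GLU = c(CB = 2, CG = 2, CD = 0, OE1 = 0, OE2 = 0),
  GLY = c(),
  HIS = c(CB = 2, CG = 0, ND1 = 1, CD2 = 1, CE1 = 1, NE2 = 0),
  ILE = c(CB = 1, CG1 = 2, CG2 = 3, CD1 = 3),
  LEU = c(CB = 2, CG = 1, CD1 = 3, CD2 = 3),
  LYS = c(CB = 2, CG = 2, CD = 2, CE = 2, NZ = 3),
  MET = c(CB = 2, CG = 2, SD = 0, CE = 3),
  PHE = c(CB = 2, CG = 0, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 1),
  PRO = c(CB = 2, CG = 2, CD = 2),
  SER = c(CB = 2, OG = 1),
  THR = c(CB = 1, OG1 = 1, CG2 = 3),
  TRP = c(CB = 2, CG = 0, CD1 = 1, CD2 = 0, NE1 = 1, CE2 = 0, CE3 = 1,
          CZ2 = 1, CZ3 = 1, CH2 = 1),
  TYR = c(CB = 2, CG = 0, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 0, OH = 1),
  VAL = c(CB = 1, CG1 = 3, CG2 = 3)
)

.ring_atoms <- list(
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("N", "CA", "CB", "CG", "CD")
)

.backbone_charge <- c(N = -0.47, CA = 0.07, C = 0.51, O = -0.51, OXT = -0.57)

.sidechain_charge <- list(
  ASP = c(CG = 0.10, OD1 = -0.55, OD2 = -0.55),
  GLU = c(CD = 0.10, OE1 = -0.55, OE2 = -0.55),
  LYS = c(NZ = 0.33),
  ARG = c(CZ = 0.20, NH1 = 0.25, NH2 = 0.25, NE = -0.10),
  HIS = c(ND1 = -0.05, NE2 = -0.05),
  SER = c(OG = -0.30),
  THR = c(OG1 = -0.30),
  TYR = c(OH = -0.30),
  CYS = c(SG = -0.20),
  ASN = c(OD1 = -0.40, ND2 = -0.30),
  GLN = c(OE1 = -0.40, NE2 = -0.30)
)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue type
# (Tien et al. 2013, theoretical column); generic fallback for non-standard
# residues.
.max_asa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)
.max_asa_fallback <- 200

#' Per-atom attribute lookup
#'
#' Returns the seven shipped attributes for one heavy atom of a standard
#' amino acid: atomic mass, B-factor placeholder (taken from the structure,
#' not this table), side-chain flag, partial charge, bonded-hydrogen count,
#' ring-membership flag and van der Waals radius.  Atom names absent from
#' the residue-specific tables fall back to element-level defaults.
#'
#' @param res_name Three-letter residue code.
#' @param atom Atom name (e.g. `"CA"`, `"OD1"`).
#' @param element Element symbol, used for defaults.
#' @return Named numeric vector `mass`, `charge`, `n_h`, `ring`, `vdw` plus
#'   logical attribute `known` (FALSE when element defaults were used).
#' @keywords internal
atom_attributes <- function(res_name, atom, element) {
  ep <- .element_props[match(element, .element_props$element), ]
  if (is.na(ep$mass)) ep <- data.frame(mass = 12.011, vdw = 1.7)
  nh_tab <- c(.backbone_nh, .sidechain_nh[[res_name]])
  ch_tab <- c(.backbone_charge, .sidechain_charge[[res_name]])
  known <- atom %in% names(nh_tab) || atom %in% names(.backbone_nh)
  n_h <- if (atom %in% names(nh_tab)) unname(nh_tab[atom]) else 0
  charge <- if (atom %in% names(ch_tab)) unname(ch_tab[atom]) else 0
  ring <- as.numeric(atom %in% .ring_atoms[[res_name]])
  out <- c(mass = ep$mass, charge = charge, n_h = n_h, ring = ring, vdw = ep$vdw)
  attr(out, "known") <- known
  out
}

#' Maximum accessible surface area per residue type
#'
#' @param res_name Three-letter residue code (vectorised).
#' @return Numeric vector of max-ASA values in Angstrom^2; unknown residue
#'   types get a generic fallback of 200 with a message.
#' @export
max_asa <- function(res_name) {
  v <- .max_asa[res_name]
  unknown <- is.na(v)
  if (any(unknown)) {
    message("max_asa: unknown residue type(s) ",
            paste(unique(res_name[unknown]), collapse = ", "),
            "; using generic fallback ", .max_asa_fallback)
    v[unknown] <- .max_asa_fallback
  }
  unname(v)
}
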
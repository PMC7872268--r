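# Ideal internal-coordinate sidechain templates. Every sidechain atom beyond
# CB is placed by NeRF from three previously placed atoms with a fixed bond
# length / bond angle and a dihedral that is either a constant or one of the
# chi torsions (plus a branch offset). Atoms whose dihedral parents are the
# chi-defining atoms make the chi round trip exact by construction.
#
# Bond lengths / angles are Engh-Huber-style values; five-membered-ring
# closure (PRO, and the fused rings of TRP/HIS) is approximate, which is
# irrelevant for torsion-space modelling.

tpl_atom <- function(name, parents, bond, angle, chi = NA, offset = 0,
                     dih = NA) {
  list(name = name, parents = parents, bond = bond, angle = angle * pi / 180,
       chi = chi, offset = offset * pi / 180, dih = dih * pi / 180)
}

SIDECHAIN_TEMPLATES <- list(
  S = list(
    tpl_atom("OG", c("N", "CA", "CB"), 1.417, 110.8, chi = 1)),
  C = list(
    tpl_atom("SG", c("N", "CA", "CB"), 1.808, 113.8, chi = 1)),
  T = list(
    tpl_atom("OG1", c("N", "CA", "CB"), 1.433, 109.6, chi = 1),
    tpl_atom("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1,
             offset = 120)),
  V = list(
    tpl_atom("CG1", c("N", "CA", "CB"), 1.527, 110.5, chi = 1),
    tpl_atom("CG2", c("N", "CA", "CB"), 1.527, 110.5, chi = 1,
             offset = 122)),
  I = list(
    tpl_atom("CG1", c("N", "CA", "CB"), 1.530, 110.4, chi = 1),
    tpl_atom("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1,
             offset = -122),
    tpl_atom("CD1", c("CA", "CB", "CG1"), 1.513, 113.8, chi = 2)),
  L = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.530, 116.3, chi = 1),
    tpl_atom("CD1", c("CA", "CB", "CG"), 1.521, 110.7, chi = 2),
    tpl_atom("CD2", c("CA", "CB", "CG"), 1.521, 110.7, chi = 2,
             offset = 122)),
  D = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.516, 112.6, chi = 1),
    tpl_atom("OD1", c("CA", "CB", "CG"), 1.249, 118.4, chi = 2),
    tpl_atom("OD2", c("CA", "CB", "CG"), 1.249, 118.4, chi = 2,
             offset = 180)),
  N = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.516, 112.6, chi = 1),
    tpl_atom("OD1", c("CA", "CB", "CG"), 1.231, 120.8, chi = 2),
    tpl_atom("ND2", c("CA", "CB", "CG"), 1.328, 116.4, chi = 2,
             offset = 180)),
  E = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    tpl_atom("CD", c("CA", "CB", "CG"), 1.516, 112.6, chi = 2),
    tpl_atom("OE1", c("CB", "CG", "CD"), 1.249, 118.4, chi = 3),
    tpl_atom("OE2", c("CB", "CG", "CD"), 1.249, 118.4, chi = 3,
             offset = 180)),
  Q = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    tpl_atom("CD", c("CA", "CB", "CG"), 1.516, 112.6, chi = 2),
    tpl_atom("OE1", c("CB", "CG", "CD"), 1.231, 120.8, chi = 3),
    tpl_atom("NE2", c("CB", "CG", "CD"), 1.328, 116.4, chi = 3,
             offset = 180)),
  M = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    tpl_atom("SD", c("CA", "CB", "CG"), 1.807, 112.7, chi = 2),
    tpl_atom("CE", c("CB", "CG", "SD"), 1.789, 100.9, chi = 3)),
  K = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    tpl_atom("CD", c("CA", "CB", "CG"), 1.520, 111.3, chi = 2),
    tpl_atom("CE", c("CB", "CG", "CD"), 1.520, 111.3, chi = 3),
    tpl_atom("NZ", c("CG", "CD", "CE"), 1.489, 111.9, chi = 4)),
  R = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    tpl_atom("CD", c("CA", "CB", "CG"), 1.520, 111.3, chi = 2),
    tpl_atom("NE", c("CB", "CG", "CD"), 1.461, 112.0, chi = 3),
    tpl_atom("CZ", c("CG", "CD", "NE"), 1.329, 124.2, chi = 4),
    tpl_atom("NH1", c("CD", "NE", "CZ"), 1.326, 120.0, dih = 0),
    tpl_atom("NH2", c("CD", "NE", "CZ"), 1.326, 120.0, dih = 180)),
  H = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.497, 113.8, chi = 1),
    tpl_atom("ND1", c("CA", "CB", "CG"), 1.378, 122.7, chi = 2),
    tpl_atom("CD2", c("CA", "CB", "CG"), 1.356, 131.0, chi = 2,
             offset = 180),
    tpl_atom("CE1", c("CB", "CG", "ND1"), 1.321, 109.0, dih = 180),
    tpl_atom("NE2", c("CB", "CG", "CD2"), 1.374, 107.0, dih = 180)),
  `F` = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.502, 113.8, chi = 1),
    tpl_atom("CD1", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2),
    tpl_atom("CD2", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2,
             offset = 180),
    tpl_atom("CE1", c("CB", "CG", "CD1"), 1.382, 120.8, dih = 180),
    tpl_atom("CE2", c("CB", "CG", "CD2"), 1.382, 120.8, dih = 180),
    tpl_atom("CZ", c("CG", "CD1", "CE1"), 1.382, 120.0, dih = 0)),
  Y = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.502, 113.8, chi = 1),
    tpl_atom("CD1", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2),
    tpl_atom("CD2", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2,
             offset = 180),
    tpl_atom("CE1", c("CB", "CG", "CD1"), 1.382, 120.8, dih = 180),
    tpl_atom("CE2", c("CB", "CG", "CD2"), 1.382, 120.8, dih = 180),
    tpl_atom("CZ", c("CG", "CD1", "CE1"), 1.382, 120.0, dih = 0),
    tpl_atom("OH", c("CD1", "CE1", "CZ"), 1.376, 119.9, dih = 180)),
  W = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.498, 113.6, chi = 1),
    tpl_atom("CD1", c("CA", "CB", "CG"), 1.365, 126.9, chi = 2),
    tpl_atom("CD2", c("CA", "CB", "CG"), 1.433, 126.6, chi = 2,
             offset = 180),
    tpl_atom("NE1", c("CB", "CG", "CD1"), 1.374, 110.2, dih = 180),
    tpl_atom("CE2", c("CB", "CG", "CD2"), 1.409, 107.2, dih = 180),
    tpl_atom("CE3", c("CB", "CG", "CD2"), 1.398, 133.9, dih = 0),
    tpl_atom("CZ2", c("CG", "CD2", "CE2"), 1.394, 122.4, dih = 180),
    tpl_atom("CZ3", c("CG", "CD2", "CE3"), 1.382, 118.6, dih = 180),
    tpl_atom("CH2", c("CD2", "CE3", "CZ3"), 1.368, 121.1, dih = 0)),
  P = list(
    tpl_atom("CG", c("N", "CA", "CB"), 1.492, 104.5, chi = 1),
    tpl_atom("CD", c("CA", "CB", "CG"), 1.503, 106.1, chi = 2))
)

# chi-defining atom quadruples per amino acid
CHI_DEFS <- list(
  S = list(c("N", "CA", "CB", "OG")),
  C = list(c("N", "CA", "CB", "SG")),
  T = list(c("N", "CA", "CB", "OG1")),
  V = list(c("N", "CA", "CB", "CG1")),
  I = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  L = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  D = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  N = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  E = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "OE1")),
  Q = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "OE1")),
  M = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
           c("CB", "CG", "SD", "CE")),
  K = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  R = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  H = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  `F` = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  Y = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  W = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  P = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"))
)

#' Number of chi torsions of an amino acid
#' @param aa one-letter code.
#' @return integer count (0 for ALA and GLY).
#' @export
n_chi <- function(aa) {
  if (aa %in% c("A", "G")) return(0L)
  defs <- CHI_DEFS[[aa]]
  if (is.null(defs)) 0L else length(defs)
}
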
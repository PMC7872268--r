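# Amino-acid code tables and ideal-geometry constants shared across modules.

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
AA1 <- structure(names(AA3), names = AA3)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of converted codes; unknown codes map to `"X"`
#'   (one-letter) or `"UNK"` (three-letter).
#' @export
aa_three_to_one <- function(x) {
  out <- AA1[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  out <- AA3[toupper(x)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Ideal backbone geometry constants
#'
#' Engh--Huber-style bond lengths (Angstrom) and bond angles (radians) used
#' whenever a backbone is rebuilt from internal coordinates, plus the default
#' trans omega torsion. Values can be overridden through the `overrides`
#' argument (names as in the returned list, angles given in degrees).
#'
#' @param overrides named list of replacement values; lengths in Angstrom,
#'   angles in degrees.
#' @return named list with bond lengths `b_n_ca`, `b_ca_c`, `b_c_n`, `b_c_o`,
#'   `b_ca_cb`, angles (radians) `a_n_ca_c`, `a_ca_c_n`, `a_c_n_ca`,
#'   `a_ca_c_o`, and `omega` (radians).
#' @export
ideal_geometry <- function(overrides = NULL) {
  geo <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_ca_cb = 1.530,
    a_n_ca_c = 111.2 * pi / 180, a_ca_c_n = 116.2 * pi / 180,
    a_c_n_ca = 121.7 * pi / 180, a_ca_c_o = 120.8 * pi / 180,
    omega = pi
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(geo)) stop("unknown geometry constant: ", nm)
      val <- overrides[[nm]]
      if (startsWith(nm, "a_") || nm == "omega") val <- val * pi / 180
      geo[[nm]] <- val
    }
  }
  geo
}

# Per-element hard-sphere radii (Angstrom) for the piecewise-linear clash
# penalty. Keys are element symbols inferred from atom names. Deliberately
# smaller than full van der Waals radii so that hydrogen-bonded backbone
# contacts (helix N...O about 2.9 A) do not register as clashes.
CLASH_RADII <- c(C = 1.60, N = 1.40, O = 1.30, S = 1.70, H = 1.00)

# Per-element Lennard-Jones-style sigma (Angstrom) for the clashing-sidechain
# counter (0.6 * sigma criterion). Config-replaceable through the functions
# that consume it.
LJ_SIGMA <- c(C = 3.50, N = 3.30, O = 3.10, S = 3.60, H = 2.40)

#' Element symbol from a PDB atom name
#'
#' First alphabetic character of the atom name; works for the heavy-atom
#' subset this package handles (C, N, O, S).
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
atom_element <- function(name) {
  sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
}

# BLOSUM62 substitution matrix (hard-coded; profiles are out of scope).
blosum62 <- local({
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  vals <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4)
  matrix(vals, 20, 20, byrow = TRUE, dimnames = list(aas, aas))
})
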
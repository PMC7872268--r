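# BackboneList: per-residue N, CA, C, O, CB with synchronised Cartesian and
# torsion (phi/psi/omega) views. The internal-coordinate tree is rooted at
# residue 1's N and runs N -> C; omega[i] is the peptide torsion between
# residue i and i + 1 (so omega[n] is undefined). phi[1] and psi[n] are
# undefined and stored as NA.

#' Construct a BackboneList from coordinate arrays
#'
#' Low-level constructor; most users go through [backbone_from_chain()],
#' [backbone_from_torsions()] or the fixture generators.
#'
#' @param seq character vector of one-letter codes (length n).
#' @param n,ca,c,o n x 3 coordinate matrices (Angstrom).
#' @param cb n x 3 matrix; rows of NA for glycine.
#' @param mode `"ideal"` (rebuilds use ideal constants) or `"measured"`.
#' @param geo geometry constants from [ideal_geometry()].
#' @return object of class `backbone_list` with torsions measured from the
#'   coordinates.
#' @export
new_backbone <- function(seq, n, ca, c, o, cb = NULL, mode = "measured",
                         geo = ideal_geometry()) {
  nres <- length(seq)
  stopifnot(nres >= 1, nrow(n) == nres, nrow(ca) == nres, nrow(c) == nres,
            nrow(o) == nres)
  if (is.null(cb)) {
    cb <- matrix(NA_real_, nres, 3)
    for (i in seq_len(nres)) {
      if (seq[i] != "G") cb[i, ] <- reconstruct_cb(n[i, ], ca[i, ], c[i, ])
    }
  }
  bb <- structure(list(seq = seq, n = n, ca = ca, c = c, o = o, cb = cb,
                       phi = rep(NA_real_, nres), psi = rep(NA_real_, nres),
                       omega = rep(NA_real_, nres), mode = mode, geo = geo),
                  class = "backbone_list")
  measure_torsions(bb)
}

#' @export
length.backbone_list <- function(x) length(x$seq)

#' @export
print.backbone_list <- function(x, ...) {
  cat("<backbone_list> ", length(x$seq), " residues: ",
      paste(x$seq, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Recompute the torsion view from Cartesian coordinates
#' @param bb a `backbone_list`.
#' @return `bb` with `phi`, `psi`, `omega` refreshed.
#' @export
measure_torsions <- function(bb) {
  nres <- length(bb$seq)
  phi <- psi <- omega <- rep(NA_real_, nres)
  if (nres >= 2) {
    for (i in seq_len(nres - 1)) {
      psi[i] <- dihedral(bb$n[i, ], bb$ca[i, ], bb$c[i, ], bb$n[i + 1, ])
      omega[i] <- dihedral(bb$ca[i, ], bb$c[i, ], bb$n[i + 1, ],
                           bb$ca[i + 1, ])
      phi[i + 1] <- dihedral(bb$c[i, ], bb$n[i + 1, ], bb$ca[i + 1, ],
                             bb$c[i + 1, ])
    }
  }
  bb$phi <- phi
  bb$psi <- psi
  bb$omega <- omega
  bb
}

#' Reconstruct a CB position from backbone atoms
#'
#' Tetrahedral construction with CA-CB 1.530 Angstrom; the chirality follows
#' the input frame and yields the L-amino-acid side (improper dihedral
#' N-CA-C-CB of about -122.5 degrees for a standard frame).
#'
#' @param n,ca,c backbone positions of one residue.
#' @param geo geometry constants.
#' @return length-3 CB position.
#' @export
reconstruct_cb <- function(n, ca, c, geo = ideal_geometry()) {
  u1 <- unitv(n - ca)
  u2 <- unitv(c - ca)
  cr <- cross3(u1, u2)
  s <- vnorm(cr)
  if (s < 1e-8) stop("collinear N, CA, C: cannot place CB")
  w <- cr / s
  # target angles N-CA-CB 110.4 deg, C-CA-CB 110.6 deg
  t1 <- cos(110.4 * pi / 180)
  t2 <- cos(110.6 * pi / 180)
  g <- sum(u1 * u2)
  det <- 1 - g^2
  a <- (t1 - g * t2) / det
  b <- (t2 - g * t1) / det
  rem <- 1 - (a^2 + b^2 + 2 * a * b * g)
  if (rem < 0) rem <- 0
  v <- a * u1 + b * u2 - sqrt(rem) * w
  ca + geo$b_ca_cb * unitv(v)
}

#' Build a BackboneList from a structure chain
#'
#' @param s a `structure3d`.
#' @param chain chain id.
#' @param range integer vector of 1-based residue indices within the chain
#'   (default: all residues).
#' @return a `backbone_list` in measured-geometry mode; missing CB atoms of
#'   non-glycine residues are reconstructed.
#' @export
backbone_from_chain <- function(s, chain, range = NULL) {
  ch <- chain_by_id(s, chain)
  if (is.null(range)) range <- seq_along(ch$residues)
  if (any(range < 1 | range > length(ch$residues))) {
    stop("residue range out of bounds")
  }
  nres <- length(range)
  n <- ca <- c_ <- o <- cb <- matrix(NA_real_, nres, 3)
  seq1 <- character(nres)
  for (k in seq_len(nres)) {
    res <- ch$residues[[range[k]]]
    miss <- setdiff(BACKBONE_ATOMS, rownames(res$atoms))
    if (length(miss) > 0) {
      stop("residue ", res$number, " (", res$name, ") is missing backbone ",
           "atom(s): ", paste(miss, collapse = ", "))
    }
    n[k, ] <- res$atoms["N", ]
    ca[k, ] <- res$atoms["CA", ]
    c_[k, ] <- res$atoms["C", ]
    o[k, ] <- res$atoms["O", ]
    seq1[k] <- res$one_letter
    if (seq1[k] != "G") {
      cb[k, ] <- if ("CB" %in% rownames(res$atoms)) res$atoms["CB", ]
                 else reconstruct_cb(n[k, ], ca[k, ], c_[k, ])
    }
  }
  new_backbone(seq1, n, ca, c_, o, cb, mode = "measured")
}

#' Build a BackboneList from torsion angles
#'
#' Residue 1 is placed in the canonical frame (N at the origin, CA on +x,
#' C in the xy-plane with positive y); all later atoms follow by NeRF chain
#' extension with ideal geometry. Re-measuring the torsions reproduces the
#' inputs to better than 1e-6 rad.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi numeric vectors (radians), one value per residue; `phi[1]`
#'   and `psi[n]` are ignored (undefined).
#' @param omega peptide torsions (radians); scalar or per-residue, default
#'   trans (pi).
#' @param geo geometry constants.
#' @return a `backbone_list` in ideal-geometry mode.
#' @export
backbone_from_torsions <- function(sequence, phi, psi, omega = pi,
                                   geo = ideal_geometry()) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  nres <- length(seq1)
  if (length(phi) != nres || length(psi) != nres) {
    stop("phi/psi length (", length(phi), "/", length(psi),
         ") does not match sequence length (", nres, ")")
  }
  if (length(omega) == 1) omega <- rep(omega, nres)
  if (length(omega) != nres) stop("omega length mismatch")

  n <- ca <- c_ <- o <- matrix(NA_real_, nres, 3)
  n[1, ] <- c(0, 0, 0)
  ca[1, ] <- c(geo$b_n_ca, 0, 0)
  c_[1, ] <- ca[1, ] + geo$b_ca_c *
    c(-cos(geo$a_n_ca_c), sin(geo$a_n_ca_c), 0)
  if (nres >= 2) {
    for (i in seq_len(nres - 1)) {
      n[i + 1, ] <- place_atom(n[i, ], ca[i, ], c_[i, ], geo$b_c_n,
                               geo$a_ca_c_n, psi[i])
      ca[i + 1, ] <- place_atom(ca[i, ], c_[i, ], n[i + 1, ], geo$b_n_ca,
                                geo$a_c_n_ca, omega[i])
      c_[i + 1, ] <- place_atom(c_[i, ], n[i + 1, ], ca[i + 1, ], geo$b_ca_c,
                                geo$a_n_ca_c, phi[i + 1])
      o[i, ] <- place_atom(n[i, ], ca[i, ], c_[i, ], geo$b_c_o, geo$a_ca_c_o,
                           psi[i] + pi)
    }
  }
  # last residue: psi undefined, place O trans-like with psi = pi
  o[nres, ] <- place_atom(n[nres, ], ca[nres, ], c_[nres, ], geo$b_c_o,
                          geo$a_ca_c_o, 0)
  new_backbone(seq1, n, ca, c_, o, mode = "ideal", geo = geo)
}

# indices of atoms moving when a torsion at residue i rotates; returns a
# list of (array, row) references encoded as a data.frame
torsion_axis <- function(bb, i, which) {
  switch(which,
    phi = list(p = bb$n[i, ], q = bb$ca[i, ]),
    psi = list(p = bb$ca[i, ], q = bb$c[i, ]),
    omega = list(p = bb$c[i, ], q = bb$n[i + 1, ]),
    stop("unknown torsion kind: ", which))
}

#' Set a phi/psi torsion, propagating downstream
#'
#' Rotates every atom downstream of the torsion bond rigidly (tree order
#' N -> C); atoms preceding the bond are untouched bit-for-bit.
#'
#' @param bb a `backbone_list`.
#' @param i residue index (1-based).
#' @param which `"phi"`, `"psi"` or `"omega"`.
#' @param value new torsion (radians).
#' @return updated `backbone_list`.
#' @export
set_torsion <- function(bb, i, which, value) {
  nres <- length(bb$seq)
  cur <- switch(which, phi = bb$phi[i], psi = bb$psi[i], omega = bb$omega[i],
                stop("unknown torsion kind: ", which))
  if (is.na(cur)) stop("torsion ", which, "[", i, "] is undefined")
  delta <- wrap_angle(value - cur)
  ax <- torsion_axis(bb, i, which)
  u <- unitv(ax$q - ax$p)
  Rt <- t(rotation_about_axis(u, delta))
  off <- ax$p - drop(ax$p %*% Rt)
  rot <- function(m) {
    m %*% Rt + matrix(off, nrow(m), 3, byrow = TRUE)
  }

  later <- if (i < nres) (i + 1):nres else integer(0)
  if (which == "phi") {
    own <- rot(rbind(bb$c[i, ], bb$o[i, ], bb$cb[i, ]))
    bb$c[i, ] <- own[1, ]
    bb$o[i, ] <- own[2, ]
    if (!is.na(bb$cb[i, 1])) bb$cb[i, ] <- own[3, ]
  } else if (which == "psi") {
    bb$o[i, ] <- drop(bb$o[i, ] %*% Rt) + off
  }
  if (length(later) > 0) {
    bb$n[later, ] <- rot(bb$n[later, , drop = FALSE])
    bb$ca[later, ] <- rot(bb$ca[later, , drop = FALSE])
    bb$c[later, ] <- rot(bb$c[later, , drop = FALSE])
    bb$o[later, ] <- rot(bb$o[later, , drop = FALSE])
    has_cb <- later[!is.na(bb$cb[later, 1])]
    if (length(has_cb) > 0) {
      bb$cb[has_cb, ] <- rot(bb$cb[has_cb, , drop = FALSE])
    }
  }
  if (which == "phi") bb$phi[i] <- wrap_angle(value)
  if (which == "psi") bb$psi[i] <- wrap_angle(value)
  if (which == "omega") bb$omega[i] <- wrap_angle(value)
  bb
}

#' Extract a contiguous sub-backbone
#' @param bb a `backbone_list`.
#' @param idx integer residue indices (must be contiguous ascending).
#' @return a `backbone_list`.
#' @export
bb_subset <- function(bb, idx) {
  new_backbone(bb$seq[idx], bb$n[idx, , drop = FALSE],
               bb$ca[idx, , drop = FALSE], bb$c[idx, , drop = FALSE],
               bb$o[idx, , drop = FALSE], bb$cb[idx, , drop = FALSE],
               mode = bb$mode, geo = bb$geo)
}

# stack selected atom coordinates of a backbone into one matrix
bb_atom_matrix <- function(bb, atoms = c("n", "ca", "c", "o")) {
  do.call(rbind, lapply(atoms, function(a) bb[[a]]))
}

#' Convert a BackboneList to a single-chain Structure
#' @param bb a `backbone_list`.
#' @param chain_id chain identifier for the output.
#' @param start_number author number of the first residue.
#' @return a `structure3d`.
#' @export
backbone_to_structure <- function(bb, chain_id = "A", start_number = 1L) {
  residues <- vector("list", length(bb$seq))
  for (i in seq_along(bb$seq)) {
    atoms <- rbind(N = bb$n[i, ], CA = bb$ca[i, ], C = bb$c[i, ],
                   O = bb$o[i, ])
    if (!is.na(bb$cb[i, 1])) atoms <- rbind(atoms, CB = bb$cb[i, ])
    residues[[i]] <- new_residue(start_number + i - 1L, "",
                                 aa_one_to_three(bb$seq[i]), atoms)
  }
  new_structure(list(list(id = chain_id, residues = residues)))
}
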
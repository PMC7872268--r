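# Simplified 3-state secondary structure assignment from backbone hydrogen
# bonding. Stands in for DSSP: the same electrostatic hydrogen-bond energy
# model, reduced to helix (H), strand (E) and coil (C).

# amide H positions: on N, 1.0 A along the bisector of (N->CA, N->C_prev);
# NA for the first residue and for proline (no amide H)
amide_h <- function(bb) {
  nres <- length(bb$seq)
  h <- matrix(NA_real_, nres, 3)
  if (nres < 2) return(h)
  for (i in 2:nres) {
    if (bb$seq[i] == "P") next
    d <- unitv(unitv(bb$n[i, ] - bb$c[i - 1, ]) +
               unitv(bb$n[i, ] - bb$ca[i, ]))
    h[i, ] <- bb$n[i, ] + d
  }
  h
}

# hydrogen-bond energy matrix: E[d, a] for donor N-H of residue d and
# acceptor C=O of residue a (kcal/mol); NA where undefined
ks_energy_matrix <- function(bb) {
  nres <- length(bb$seq)
  h <- amide_h(bb)
  E <- matrix(NA_real_, nres, nres)
  q <- 0.084 * 332
  for (d in seq_len(nres)) {
    if (is.na(h[d, 1])) next
    for (a in seq_len(nres)) {
      if (abs(d - a) < 2) next
      r_on <- vnorm(bb$o[a, ] - bb$n[d, ])
      r_ch <- vnorm(bb$c[a, ] - h[d, ])
      r_oh <- vnorm(bb$o[a, ] - h[d, ])
      r_cn <- vnorm(bb$c[a, ] - bb$n[d, ])
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) {
        E[d, a] <- -9.9
      } else {
        E[d, a] <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      }
    }
  }
  E
}

#' Assign secondary structure from backbone geometry
#'
#' Hydrogen bonds are detected with the Kabsch--Sander electrostatic model
#' (bond if E < -0.5 kcal/mol, amide H built from the backbone). Residues in
#' runs of i -> i+4 bonded turns become H, bridge-paired residues become E,
#' everything else C. Chains shorter than 5 residues are all C.
#'
#' @param bb a `backbone_list`.
#' @return character string over `{H, E, C}` of the same length as `bb`.
#' @export
assign_ss <- function(bb) {
  nres <- length(bb$seq)
  if (nres < 5) return(paste(rep("C", nres), collapse = ""))
  E <- ks_energy_matrix(bb)
  hb <- !is.na(E) & E < -0.5
  ss <- rep("C", nres)

  # 4-turns: donor i+4 -> acceptor i; two consecutive turns make a helix
  turn4 <- rep(FALSE, nres)
  for (i in seq_len(nres - 4)) turn4[i] <- hb[i + 4, i]
  for (i in seq_len(nres - 5)) {
    if (turn4[i] && turn4[i + 1]) ss[(i + 1):(i + 4)] <- "H"
  }

  # bridges (antiparallel: mutual bonds or enclosing pair; parallel: offset)
  bridge <- matrix(FALSE, nres, nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (abs(i - j) < 3) next
      anti <- (hb[i, j] && hb[j, i]) ||
        (i > 1 && j < nres && i + 1 <= nres && j - 1 >= 1 &&
           hb[i - 1, j + 1] && hb[j - 1, i + 1])
      par <- (j > 1 && j < nres && hb[i, j - 1] && hb[j + 1, i]) ||
        (i > 1 && i < nres && hb[j, i - 1] && hb[i + 1, j])
      if (anti || par) bridge[i, j] <- TRUE
    }
  }
  for (i in seq_len(nres)) {
    if (ss[i] != "H" && any(bridge[i, ])) ss[i] <- "E"
  }
  paste(ss, collapse = "")
}
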
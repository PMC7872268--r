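# Rotamer construction and energies: building sidechain atoms from chi
# angles, measuring chi from coordinates, the SCWRL3-style piecewise-linear
# pairwise energy (rigid) and its flexible-rotamer log-sum-exp combination,
# frame energies and disulfide detection.

#' Build a rigid rotamer from a backbone frame and chi angles
#'
#' @param aa one-letter code (not `"G"`; `"A"` yields a CB-only rotamer).
#' @param frame list with `n`, `ca`, `c` positions and optionally `cb`
#'   (reconstructed when absent).
#' @param chi numeric chi angles in degrees, length [n_chi()] of `aa`.
#' @param probability library probability (stored; used for self energies).
#' @param res_id residue index within the model (for frame exclusions).
#' @param K probability-to-energy scale (self energy -K ln p).
#' @return object of class `rotamer` with fields `aa`, `atoms` (sidechain
#'   atoms including CB, named rows), `chi`, `probability`, `self_energy`,
#'   `res_id`, `frame`.
#' @export
build_rotamer <- function(aa, frame, chi = numeric(0), probability = 1,
                          res_id = NA_integer_, K = 1) {
  aa <- toupper(aa)
  if (aa == "G") stop("glycine has no sidechain rotamer")
  cb <- if (!is.null(frame$cb) && !is.na(frame$cb[1])) frame$cb
        else reconstruct_cb(frame$n, frame$ca, frame$c)
  placed <- list(N = frame$n, CA = frame$ca, C = frame$c, CB = cb)
  if (aa != "A") {
    nch <- n_chi(aa)
    if (length(chi) != nch) {
      stop(aa, " needs ", nch, " chi angle(s), got ", length(chi))
    }
    for (at in SIDECHAIN_TEMPLATES[[aa]]) {
      dih <- if (!is.na(at$chi)) chi[at$chi] * pi / 180 + at$offset
             else at$dih
      placed[[at$name]] <- place_atom(placed[[at$parents[1]]],
                                      placed[[at$parents[2]]],
                                      placed[[at$parents[3]]],
                                      at$bond, at$angle, dih)
    }
  }
  side_names <- setdiff(names(placed), c("N", "CA", "C"))
  atoms <- do.call(rbind, placed[side_names])
  rownames(atoms) <- side_names
  structure(list(aa = aa, atoms = atoms, chi = chi,
                 probability = probability,
                 self_energy = -K * log(max(probability, 1e-12)),
                 res_id = res_id,
                 frame = list(n = frame$n, ca = frame$ca, c = frame$c)),
            class = "rotamer")
}

#' Measure chi angles of a residue's atoms
#'
#' @param aa one-letter code.
#' @param atoms matrix with named rows covering at least the chi-defining
#'   atoms (backbone N, CA included).
#' @return numeric chi angles in degrees (length [n_chi()]), NA where atoms
#'   are missing.
#' @export
measure_chi <- function(aa, atoms) {
  defs <- CHI_DEFS[[toupper(aa)]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(d) {
    if (!all(d %in% rownames(atoms))) return(NA_real_)
    dihedral(atoms[d[1], ], atoms[d[2], ], atoms[d[3], ], atoms[d[4], ]) *
      180 / pi
  }, 0)
}

rotamer_chi_atoms <- function(rot) {
  rbind(N = rot$frame$n, CA = rot$frame$ca, C = rot$frame$c, rot$atoms)
}

#' Construct a flexible rotamer (FRM)
#'
#' Sub-rotamer 1 is the central conformation; the others perturb one chi at a
#' time by +/- one library sigma (capped at 1 + 2 * n_chi sub-rotamers).
#' Sub-rotamer weights are Gaussian in the perturbation (central weight 1,
#' perturbed exp(-1/2)), normalized.
#'
#' @param aa,frame,chi,probability,res_id,K as in [build_rotamer()].
#' @param sigmas per-chi standard deviations in degrees.
#' @return object of class `flexible_rotamer` with `subs` (list of
#'   [build_rotamer()] results) and `weights`.
#' @export
build_flexible_rotamer <- function(aa, frame, chi, sigmas, probability = 1,
                                   res_id = NA_integer_, K = 1) {
  subs <- list(build_rotamer(aa, frame, chi, probability, res_id, K))
  w <- 1
  nch <- length(chi)
  if (nch > 0) {
    for (k in seq_len(nch)) {
      for (sgn in c(-1, 1)) {
        chi_k <- chi
        chi_k[k] <- chi_k[k] + sgn * sigmas[k]
        subs[[length(subs) + 1L]] <-
          build_rotamer(aa, frame, chi_k, probability, res_id, K)
        w <- c(w, exp(-0.5))
      }
    }
  }
  structure(list(aa = aa, subs = subs, weights = w / sum(w),
                 probability = probability,
                 self_energy = subs[[1]]$self_energy, res_id = res_id),
            class = "flexible_rotamer")
}

rigid_atom_energy <- function(pos_a, elem_a, pos_b, elem_b,
                              radii = CLASH_RADII) {
  if (nrow(pos_a) == 0 || nrow(pos_b) == 0) return(0)
  d <- sqrt(pmax(cross_dist2(pos_a, pos_b), 0))
  R <- outer(radii[elem_a], radii[elem_b], `+`)
  sum(clash_penalty(d, R)[d < R])
}

rotamer_elements <- function(rot) atom_element(rownames(rot$atoms))

#' Pairwise energy between two rotamers
#'
#' Rigid x rigid: SCWRL3-style piecewise-linear repulsion summed over
#' inter-rotamer heavy-atom pairs. If either operand is flexible the
#' energies of all sub-rotamer pairs are combined thermodynamically:
#' E = -(1/beta) ln sum w_k w_l exp(-beta E_kl).
#'
#' @param a,b `rotamer` or `flexible_rotamer` objects.
#' @param beta inverse temperature for the FRM combination (default 1).
#' @param radii hard-sphere radius table.
#' @return energy (>= 0 for the default repulsive function).
#' @export
pairwise_energy <- function(a, b, beta = 1, radii = CLASH_RADII) {
  subs_a <- if (inherits(a, "flexible_rotamer")) a$subs else list(a)
  w_a <- if (inherits(a, "flexible_rotamer")) a$weights else 1
  subs_b <- if (inherits(b, "flexible_rotamer")) b$subs else list(b)
  w_b <- if (inherits(b, "flexible_rotamer")) b$weights else 1
  if (length(subs_a) == 1 && length(subs_b) == 1) {
    return(rigid_atom_energy(subs_a[[1]]$atoms, rotamer_elements(subs_a[[1]]),
                             subs_b[[1]]$atoms, rotamer_elements(subs_b[[1]]),
                             radii))
  }
  acc <- 0
  for (k in seq_along(subs_a)) {
    ea <- rotamer_elements(subs_a[[k]])
    for (l in seq_along(subs_b)) {
      E <- rigid_atom_energy(subs_a[[k]]$atoms, ea, subs_b[[l]]$atoms,
                             rotamer_elements(subs_b[[l]]), radii)
      acc <- acc + w_a[k] * w_b[l] * exp(-beta * E)
    }
  }
  -log(acc) / beta
}

#' Energy of a rotamer against the fixed frame
#'
#' The frame is the part of the model that stays in place (backbone plus
#' complete sidechains). The rotamer's own residue and the directly bonded
#' peptide atoms of its +/- 1 neighbours (C/O of the preceding, N/CA of the
#' following residue) are excluded.
#'
#' @param rot a `rotamer` or `flexible_rotamer`.
#' @param frame list with `pos` (m x 3), `elem`, `res` (residue ids) and
#'   `name` (atom names).
#' @param beta,radii as in [pairwise_energy()].
#' @return energy.
#' @export
frame_energy <- function(rot, frame, beta = 1, radii = CLASH_RADII) {
  res_id <- rot$res_id
  keep <- rep(TRUE, length(frame$res))
  if (!is.na(res_id)) {
    keep <- keep & frame$res != res_id
    keep <- keep & !(frame$res == res_id - 1 & frame$name %in% c("C", "O"))
    keep <- keep & !(frame$res == res_id + 1 & frame$name %in% c("N", "CA"))
  }
  pos <- frame$pos[keep, , drop = FALSE]
  elem <- frame$elem[keep]
  subs <- if (inherits(rot, "flexible_rotamer")) rot$subs else list(rot)
  w <- if (inherits(rot, "flexible_rotamer")) rot$weights else 1
  if (length(subs) == 1) {
    return(rigid_atom_energy(subs[[1]]$atoms, rotamer_elements(subs[[1]]),
                             pos, elem, radii))
  }
  acc <- 0
  for (k in seq_along(subs)) {
    E <- rigid_atom_energy(subs[[k]]$atoms, rotamer_elements(subs[[k]]),
                           pos, elem, radii)
    acc <- acc + w[k] * exp(-beta * E)
  }
  -log(acc) / beta
}

sg_position <- function(rot) {
  if (inherits(rot, "flexible_rotamer")) rot <- rot$subs[[1]]
  if (!"SG" %in% rownames(rot$atoms)) return(NULL)
  rot$atoms["SG", ]
}

#' Detect disulfide-bonded cysteine pairs
#'
#' A pair is a candidate when some rotamer combination puts the two SG atoms
#' within 1.8-2.5 Angstrom. Pairs are selected greedily by SG-SG distance
#' closest to 2.05 Angstrom, each cysteine used at most once.
#'
#' @param cys_groups list of `list(pos = residue index, rotamers = list)`;
#'   rotamers may be rigid or flexible (central sub-rotamer used).
#' @return list of `list(i, j, rot_i, rot_j, sg_dist)` giving the positions
#'   (indices into `cys_groups`) and selected rotamer indices.
#' @export
detect_disulfides <- function(cys_groups) {
  ng <- length(cys_groups)
  if (ng < 2) return(list())
  cands <- list()
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      best <- NULL
      for (ri in seq_along(cys_groups[[i]]$rotamers)) {
        sgi <- sg_position(cys_groups[[i]]$rotamers[[ri]])
        if (is.null(sgi)) next
        for (rj in seq_along(cys_groups[[j]]$rotamers)) {
          sgj <- sg_position(cys_groups[[j]]$rotamers[[rj]])
          if (is.null(sgj)) next
          d <- vnorm(sgi - sgj)
          if (d >= 1.8 && d <= 2.5) {
            if (is.null(best) || abs(d - 2.05) < abs(best$sg_dist - 2.05)) {
              best <- list(i = i, j = j, rot_i = ri, rot_j = rj, sg_dist = d)
            }
          }
        }
      }
      if (!is.null(best)) cands[[length(cands) + 1L]] <- best
    }
  }
  if (length(cands) == 0) return(list())
  ord <- order(vapply(cands, function(x) abs(x$sg_dist - 2.05), 0),
               vapply(cands, function(x) x$i, 0),
               vapply(cands, function(x) x$j, 0))
  used <- rep(FALSE, ng)
  out <- list()
  for (k in ord) {
    cand <- cands[[k]]
    if (used[cand$i] || used[cand$j]) next
    used[c(cand$i, cand$j)] <- TRUE
    out[[length(out) + 1L]] <- cand
  }
  out
}
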
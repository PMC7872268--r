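# Sidechain reconstruction pipeline: rotamer groups for incomplete residues,
# fixed frame from backbone + complete sidechains, disulfide detection,
# energy evaluation, complexity reduction (edge decomposition + DEE), exact
# packing, optional sub-rotamer optimization, and evaluation metrics.

residue_template_atoms <- function(aa) {
  if (aa == "G") return(BACKBONE_ATOMS)
  if (aa == "A") return(c(BACKBONE_ATOMS, "CB"))
  c(BACKBONE_ATOMS, "CB",
    vapply(SIDECHAIN_TEMPLATES[[aa]], `[[`, "", "name"))
}

residue_is_complete <- function(res) {
  aa <- res$one_letter
  if (!aa %in% names(AA3)) return(TRUE)
  all(residue_template_atoms(aa) %in% rownames(res$atoms))
}

# fixed-frame atom table from a chain; include_side: per-residue logical,
# whether that residue's sidechain atoms (beyond CB) are part of the frame
build_frame_table <- function(ch, include_side) {
  pos <- NULL
  res <- integer(0)
  name <- character(0)
  for (i in seq_along(ch$residues)) {
    r <- ch$residues[[i]]
    keep <- rownames(r$atoms) %in% c(BACKBONE_ATOMS, "CB")
    if (include_side[i]) keep <- rep(TRUE, nrow(r$atoms))
    pos <- rbind(pos, r$atoms[keep, , drop = FALSE])
    res <- c(res, rep(i, sum(keep)))
    name <- c(name, rownames(r$atoms)[keep])
  }
  list(pos = pos, res = res, name = name, elem = atom_element(name))
}

#' Rebuild sidechains of a structure
#'
#' Follows the standard packing pipeline: rotamer groups are extracted for
#' every residue with an incomplete sidechain (or all residues with
#' `rebuild_all = TRUE`); backbone atoms and complete sidechains form the
#' fixed frame; disulfide-capable cysteine pairs are detected and fixed;
#' self (library + frame) and pairwise energies populate a rotamer graph
#' which is reduced by edge decomposition and Goldstein DEE and solved
#' exactly (tree decomposition, with A* and Monte Carlo fallbacks). In FRM
#' mode a final sub-rotamer optimization relieves residual clashes.
#'
#' @param s a `structure3d` (first chain is processed).
#' @param lib a `rotamer_library`.
#' @param mode `"RRM"` or `"FRM"`.
#' @param coverage rotamer-probability coverage (default 0.98).
#' @param K probability-to-energy scale (default 1).
#' @param rebuild_all rebuild even complete sidechains.
#' @param eps edge-decomposition tolerance (default 0.01).
#' @param radii hard-sphere radius table.
#' @return the structure with rebuilt sidechains.
#' @export
reconstruct_sidechains <- function(s, lib, mode = "FRM", coverage = 0.98,
                                   K = 1, rebuild_all = FALSE, eps = 0.01,
                                   radii = CLASH_RADII) {
  mode <- match.arg(mode, c("RRM", "FRM"))
  ch <- s$chains[[1]]
  nres <- length(ch$residues)
  bb <- backbone_from_chain(s, ch$id)
  complete <- vapply(ch$residues, residue_is_complete, TRUE)
  targets <- which(if (rebuild_all) bb$seq != "G" else
                   (!complete & bb$seq != "G"))
  if (length(targets) == 0) return(s)

  frame_tab <- build_frame_table(ch, include_side = !seq_len(nres) %in%
                                   targets)
  groups <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    i <- targets[t]
    frame_i <- list(n = bb$n[i, ], ca = bb$ca[i, ], c = bb$c[i, ],
                    cb = bb$cb[i, ])
    groups[[t]] <- get_rotamer_group(lib, bb$seq[i], bb$phi[i], bb$psi[i],
                                     frame_i, mode = mode,
                                     coverage = coverage, res_id = i, K = K)
  }

  # disulfides: detect among targeted cysteines, then fix the chosen pair
  fixed_rot <- rep(NA_integer_, length(targets))
  cys_t <- which(bb$seq[targets] == "C")
  if (length(cys_t) >= 2) {
    cys_groups <- lapply(cys_t, function(t) {
      list(pos = targets[t], rotamers = groups[[t]])
    })
    for (pair in detect_disulfides(cys_groups)) {
      fixed_rot[cys_t[pair$i]] <- pair$rot_i
      fixed_rot[cys_t[pair$j]] <- pair$rot_j
    }
  }
  for (t in which(!is.na(fixed_rot))) {
    groups[[t]] <- groups[[t]][fixed_rot[t]]
  }

  self <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    self[[t]] <- vapply(groups[[t]], function(r) {
      r$self_energy + frame_energy(r, frame_tab, radii = radii)
    }, 0)
  }
  edges <- list()
  for (a in seq_along(targets)) {
    for (b in seq_len(a - 1L)) {
      # skip pairs that cannot interact (CB-CB distance gate)
      d_cb <- sqrt(sum((bb$ca[targets[a], ] - bb$ca[targets[b], ])^2))
      if (d_cb > 16) next
      m <- matrix(0, length(groups[[b]]), length(groups[[a]]))
      for (rb in seq_along(groups[[b]])) {
        for (ra in seq_along(groups[[a]])) {
          m[rb, ra] <- pairwise_energy(groups[[b]][[rb]], groups[[a]][[ra]],
                                       radii = radii)
        }
      }
      if (any(m != 0)) {
        edges[[length(edges) + 1L]] <- list(i = b, j = a, m = m)
      }
    }
  }

  g <- rotamer_graph(self, edges, ids = targets)
  dec <- edge_decompose(g, eps)
  dee <- dee_goldstein(dec$graph)
  sol <- tryCatch(solve_treepack(dee$graph),
                  error = function(e) {
                    tryCatch(solve_astar(dee$graph, 0)$solutions[[1]],
                             error = function(e2) {
                               solve_monte_carlo(dee$graph, steps = 5000,
                                                 seed = 1)
                             })
                  })
  chosen <- lapply(seq_along(targets), function(t) {
    groups[[t]][[dee$kept[[t]][sol$assignment[t]]]]
  })
  if (mode == "FRM") {
    opt <- subrotamer_optimize(chosen, frame = frame_tab, radii = radii)
    chosen <- opt$rotamers
  } else {
    chosen <- lapply(chosen, function(r) {
      if (inherits(r, "flexible_rotamer")) r$subs[[1]] else r
    })
  }

  for (t in seq_along(targets)) {
    i <- targets[t]
    r <- ch$residues[[i]]
    bbatoms <- r$atoms[rownames(r$atoms) %in% BACKBONE_ATOMS, ,
                       drop = FALSE]
    ch$residues[[i]]$atoms <- rbind(bbatoms, chosen[[t]]$atoms)
    ch$residues[[i]]$occupancy <- NULL
    ch$residues[[i]]$bfactor <- NULL
  }
  s$chains[[1]] <- ch
  s
}

chi1_of_residue <- function(res) {
  aa <- res$one_letter
  if (is.null(CHI_DEFS[[aa]])) return(NA_real_)
  measure_chi(aa, res$atoms)[1]
}

#' Fraction of chi1 angles within a tolerance of a reference
#'
#' Residues lacking a chi1 in either structure are skipped; the difference
#' is circular. Residues with symmetric terminal groups keep their single
#' chi1 definition (the gamma atom is unique for all of them).
#'
#' @param model,reference `structure3d`s with identical residue composition
#'   (first chains compared).
#' @param tol tolerance in degrees (default 20).
#' @return fraction in `[0, 1]` (NaN when no residue has a chi1).
#' @export
chi1_fraction <- function(model, reference, tol = 20) {
  rm_ <- model$chains[[1]]$residues
  rr <- reference$chains[[1]]$residues
  stopifnot(length(rm_) == length(rr))
  n_ok <- 0L
  n_tot <- 0L
  for (i in seq_along(rm_)) {
    c_m <- chi1_of_residue(rm_[[i]])
    c_r <- chi1_of_residue(rr[[i]])
    if (is.na(c_m) || is.na(c_r)) next
    n_tot <- n_tot + 1L
    if (circ_diff_deg(c_m, c_r) <= tol) n_ok <- n_ok + 1L
  }
  n_ok / n_tot
}

#' Count residues with clashing sidechains
#'
#' A residue counts when at least one of its sidechain atoms lies closer
#' than `factor * sigma_pair` to any atom of a different residue, where
#' `sigma_pair` is the arithmetic mean of the two atoms' sigma values.
#' Backbone/CB contacts between peptide-bonded neighbours are excluded.
#'
#' @param s a `structure3d`.
#' @param factor multiplier on sigma (default 0.6).
#' @param sigma_table named per-element sigma values in Angstrom
#'   (config-replaceable; defaults bundled).
#' @return integer count of clashing residues.
#' @export
count_clashing_sidechains <- function(s, factor = 0.6,
                                      sigma_table = LJ_SIGMA) {
  residues <- list()
  for (ch in s$chains) residues <- c(residues, ch$residues)
  nres <- length(residues)
  if (factor <= 0 || nres < 2) return(0L)
  pos <- NULL
  res_id <- integer(0)
  name <- character(0)
  for (i in seq_len(nres)) {
    a <- residues[[i]]$atoms
    pos <- rbind(pos, a)
    res_id <- c(res_id, rep(i, nrow(a)))
    name <- c(name, rownames(a))
  }
  elem <- atom_element(name)
  if (any(!elem %in% names(sigma_table))) {
    stop("atom type(s) missing from the sigma table: ",
         paste(unique(elem[!elem %in% names(sigma_table)]), collapse = ", "))
  }
  sig <- sigma_table[elem]
  is_side <- !name %in% BACKBONE_ATOMS
  is_bb_like <- name %in% c(BACKBONE_ATOMS, "CB")
  clashing <- rep(FALSE, nres)
  d2 <- cross_dist2(pos, pos)
  thr <- (factor * outer(sig, sig, `+`) / 2)^2
  hits <- which(d2 < thr, arr.ind = TRUE)
  for (h in seq_len(nrow(hits))) {
    a <- hits[h, 1]
    b <- hits[h, 2]
    if (res_id[a] == res_id[b]) next
    if (!is_side[a]) next
    if (abs(res_id[a] - res_id[b]) == 1 && is_bb_like[a] && is_bb_like[b]) {
      next
    }
    clashing[res_id[a]] <- TRUE
  }
  sum(clashing)
}
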
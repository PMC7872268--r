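# Deterministic synthetic-structure and scenario generators. Everything a
# test needs is built in code: ideal secondary-structure elements, a
# miniature rotamer library, toy proteins with packed sidechains, loop
# modelling cases, scored decoy sets and miniature fragment databases.
# Fixtures are geometric, not biological.

#' Ideal alpha helix
#'
#' phi = -57, psi = -47 degrees throughout; the sequence is sampled
#' reproducibly from the 20 amino acids unless given.
#'
#' @param n number of residues.
#' @param seed RNG seed for the sequence draw.
#' @param sequence optional explicit sequence (overrides sampling).
#' @return a `backbone_list`.
#' @export
make_ideal_helix <- function(n, seed = 1, sequence = NULL) {
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- paste(sample(AA20, n, replace = TRUE), collapse = "")
  }
  backbone_from_torsions(sequence, rep(-57 * pi / 180, n),
                         rep(-47 * pi / 180, n))
}

#' Ideal extended strand (phi = psi = 180 degrees)
#' @inheritParams make_ideal_helix
#' @return a `backbone_list`.
#' @export
make_extended_strand <- function(n, seed = 1, sequence = NULL) {
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- paste(sample(AA20, n, replace = TRUE), collapse = "")
  }
  backbone_from_torsions(sequence, rep(pi, n), rep(pi, n))
}

#' Two-stranded antiparallel beta hairpin
#'
#' Two beta strands joined by a tight turn; strand torsions are tuned so the
#' Kabsch--Sander model detects the cross-strand hydrogen bonds.
#'
#' @param n_strand residues per strand (default 5).
#' @param seed RNG seed for the sequence draw.
#' @return a `backbone_list`.
#' @export
make_hairpin <- function(n_strand = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_strand + 2
  sequence <- paste(sample(setdiff(AA20, c("P")), n, replace = TRUE),
                    collapse = "")
  deg <- pi / 180
  phi <- c(rep(-120 * deg, n_strand), 90 * deg, -120 * deg,
           rep(-120 * deg, n_strand))
  psi <- c(rep(130 * deg, n_strand), -120 * deg, 0 * deg,
           rep(130 * deg, n_strand))
  backbone_from_torsions(sequence, phi, psi)
}

#' Miniature backbone-independent rotamer library
#'
#' Hand-constructed entries: canonical chi1 wells (-65, 180, 62 degrees,
#' probabilities 0.5/0.3/0.2) with trans higher chis and 8-degree sigmas.
#' Suited to fixtures; not trained from data.
#'
#' @return a `rotamer_library` (backbone-independent).
#' @export
fixture_rotamer_library <- function() {
  entries <- list()
  chi1_wells <- c(-65, 180, 62)
  probs <- c(0.5, 0.3, 0.2)
  for (aa in AA20) {
    nch <- n_chi(aa)
    if (aa == "A") {
      entries[[aa]] <- list(list(probability = 1, chi = numeric(0),
                                 sigma = numeric(0)))
      next
    }
    if (nch == 0) next
    # aromatics prefer perpendicular chi2; everything else trans
    chi2_wells <- if (aa %in% c("F", "Y", "W", "H")) c(90, -90) else 180
    es <- list()
    for (k in seq_along(chi1_wells)) {
      for (c2 in chi2_wells) {
        chi <- c(chi1_wells[k], c2, rep(180, 2))[seq_len(nch)]
        if (aa == "P") chi <- c(25, -30)[seq_len(nch)]  # ring pucker-ish
        es[[length(es) + 1L]] <- list(
          probability = probs[k] / length(chi2_wells), chi = chi,
          sigma = rep(8, nch))
        if (aa == "P") break
      }
      if (aa == "P") break
    }
    entries[[aa]] <- es
  }
  new_rotamer_library(entries, backbone_dependent = FALSE)
}

#' Toy protein with packed sidechains
#'
#' Helix-loop-helix backbone with library rotamers placed one residue at a
#' time, rejecting rotamers that clash with anything already placed. The
#' result passes [count_clashing_sidechains()] with zero clashes.
#'
#' @param n_res total residues (>= 12).
#' @param seed RNG seed (sequence and rotamer draws).
#' @param lib rotamer library (default [fixture_rotamer_library()]).
#' @param sequence optional explicit sequence.
#' @return a `structure3d` with full sidechains.
#' @export
make_toy_protein <- function(n_res = 24, seed = 1,
                             lib = fixture_rotamer_library(),
                             sequence = NULL) {
  stopifnot(n_res >= 12)
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- paste(sample(setdiff(AA20, c("P", "G")), n_res,
                             replace = TRUE), collapse = "")
  }
  n1 <- max(4L, floor(0.4 * n_res))
  n_loop <- 4L
  n2 <- n_res - n1 - n_loop
  deg <- pi / 180
  phi <- c(rep(-57 * deg, n1), c(-67, -65, -117, -74) * deg,
           rep(-57 * deg, n2))
  psi <- c(rep(-47 * deg, n1), c(135, 126, 142, 99) * deg,
           rep(-47 * deg, n2))
  bb <- backbone_from_torsions(sequence, phi, psi)
  s <- backbone_to_structure(bb)
  ch <- s$chains[[1]]

  placed <- build_frame_table(ch, include_side = rep(FALSE, n_res))
  for (i in seq_len(n_res)) {
    aa <- bb$seq[i]
    if (aa %in% c("G", "A")) next
    frame_i <- list(n = bb$n[i, ], ca = bb$ca[i, ], c = bb$c[i, ],
                    cb = bb$cb[i, ])
    flex <- get_rotamer_group(lib, aa, bb$phi[i], bb$psi[i], frame_i,
                              mode = "FRM", coverage = 1, res_id = i)
    rots <- do.call(c, lapply(flex, `[[`, "subs"))  # centrals + perturbed
    # least-clashing rotamer among those that satisfy the hard 0.6 sigma
    # overlap criterion against everything placed so far
    hard_ok <- vapply(rots, function(r) {
      ats <- r$atoms[!rownames(r$atoms) %in% "CB", , drop = FALSE]
      if (nrow(ats) == 0) return(TRUE)
      sig_a <- LJ_SIGMA[atom_element(rownames(ats))]
      sig_b <- LJ_SIGMA[placed$elem]
      d2 <- cross_dist2(ats, placed$pos)
      thr <- (0.6 * outer(sig_a, sig_b, `+`) / 2)^2
      viol <- d2 < thr
      # ignore contacts inside the own residue
      viol[, placed$res == i] <- FALSE
      !any(viol)
    }, TRUE)
    if (!any(hard_ok)) {
      stop("could not place a clash-free rotamer at residue ", i,
           " (", aa, "); try another seed")
    }
    rots <- rots[hard_ok]
    energies <- vapply(rots, function(r) frame_energy(r, placed), 0)
    ok <- rots[[which.min(energies)]]
    extra <- ok$atoms[!rownames(ok$atoms) %in% "CB", , drop = FALSE]
    ch$residues[[i]]$atoms <- rbind(ch$residues[[i]]$atoms, extra)
    placed$pos <- rbind(placed$pos, extra)
    placed$res <- c(placed$res, rep(i, nrow(extra)))
    placed$name <- c(placed$name, rownames(extra))
    placed$elem <- c(placed$elem, atom_element(rownames(extra)))
  }
  s$chains[[1]] <- ch
  if (count_clashing_sidechains(s) > 0) {
    stop("toy protein generation produced clashing sidechains; ",
         "try another seed")
  }
  s
}

#' Cut a loop out of a structure to create a modelling case
#'
#' @param s a `structure3d` (first chain used).
#' @param span integer residue indices to remove (interior; not touching
#'   either terminus).
#' @return list with `mh` (a `modelling_handle` missing the span) and
#'   `reference` (the native span as a `backbone_list`, stems included).
#' @export
make_loop_case <- function(s, span) {
  ch <- s$chains[[1]]
  nres <- length(ch$residues)
  if (min(span) <= 1 || max(span) >= nres) {
    stop("span must be interior (not touching the termini)")
  }
  bb <- backbone_from_chain(s, ch$id)
  nt <- nres
  mh <- structure(list(
    target_seq = bb$seq, chain_id = ch$id,
    n = bb$n, ca = bb$ca, c = bb$c, o = bb$o, cb = bb$cb,
    present = rep(TRUE, nt),
    sidechains = vector("list", nt),
    template_ss = strsplit(assign_ss(bb), "")[[1]],
    gaps = list(), trimmed = integer(0)),
    class = "modelling_handle")
  for (i in span) {
    mh$n[i, ] <- NA_real_
    mh$ca[i, ] <- NA_real_
    mh$c[i, ] <- NA_real_
    mh$o[i, ] <- NA_real_
    mh$cb[i, ] <- NA_real_
    mh$present[i] <- FALSE
    mh$template_ss[i] <- NA_character_
  }
  mh$gaps <- list(list(before = min(span) - 1L, after = max(span) + 1L,
                       seq = paste(bb$seq[span], collapse = "")))
  reference <- bb_subset(bb, (min(span) - 1L):(max(span) + 1L))
  list(mh = mh, reference = reference)
}

#' Generate a labelled loop decoy set
#'
#' Perturbs the reference loop's interior torsions by Gaussian noise
#' (cycling through the sigma ladder), re-closes with CCD and labels each
#' decoy with its interior CA-RMSD to the reference.
#'
#' @param reference a `backbone_list` spanning stem..stem.
#' @param n number of decoys.
#' @param seed RNG seed.
#' @param sigmas ladder of torsion perturbations in degrees.
#' @return list of `list(loop, rmsd)`.
#' @export
make_decoy_set <- function(reference, n = 30, seed = 1,
                           sigmas = c(0, 5, 10, 20, 40)) {
  set.seed(seed)
  L <- length(reference$seq)
  n_anchor <- rbind(reference$n[1, ], reference$ca[1, ], reference$c[1, ])
  c_anchor <- rbind(reference$n[L, ], reference$ca[L, ], reference$c[L, ])
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sig <- sigmas[((k - 1) %% length(sigmas)) + 1] * pi / 180
    loop <- reference
    if (sig > 0) {
      for (i in seq_len(L)) {
        if (!is.na(loop$phi[i])) {
          loop <- set_torsion(loop, i, "phi",
                              loop$phi[i] + stats::rnorm(1, 0, sig))
        }
        if (!is.na(loop$psi[i]) && i < L) {
          loop <- set_torsion(loop, i, "psi",
                              loop$psi[i] + stats::rnorm(1, 0, sig))
        }
      }
      loop <- ccd_close(loop, n_anchor, c_anchor)$loop
    }
    inner <- 2:(L - 1)
    rmsd <- sqrt(mean(rowSums((loop$ca[inner, , drop = FALSE] -
                                 reference$ca[inner, , drop = FALSE])^2)))
    out[[k]] <- list(loop = loop, rmsd = rmsd)
  }
  out
}

#' Build a miniature StructureDB + FragDB from structures
#'
#' Wraps [db_add_chain()] and [fragdb_add_fragments()] for fragment lengths
#' 3..14 with the default bins (distance 1 Angstrom, angles 20 degrees) and
#' redundancy threshold 1 Angstrom.
#'
#' @param structures list of `structure3d` (first chain of each is added).
#' @param lengths fragment lengths to index (default 3:14).
#' @param rmsd_thresh redundancy threshold (default 1.0).
#' @return list with `sdb` and `fdb`.
#' @export
make_mini_db <- function(structures, lengths = 3:14, rmsd_thresh = 1.0) {
  if (length(structures) == 0) stop("need at least one structure")
  sdb <- db_new()
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    bb <- backbone_from_chain(s, s$chains[[1]]$id)
    sdb <- db_add_chain(sdb, paste0("fix", k), s$chains[[1]]$id, bb)$db
  }
  fdb <- fragdb_new(1.0, 20)
  for (L in lengths) {
    fdb <- fragdb_add_fragments(fdb, L, rmsd_thresh, sdb)$fdb
  }
  list(sdb = sdb, fdb = fdb)
}
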
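# Knowledge-based statistical potentials trained from a StructureDB by
# inverse Boltzmann statistics: E(bin | ctx) = -ln[(N_obs + p) / (N_ref + p)]
# with pseudo-count p = 1 and a context-free reference state (expected counts
# if every context followed the pooled bin distribution).

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")

#' Inverse-Boltzmann energies from observation counts
#'
#' @param obs matrix of counts, contexts in rows, bins in columns.
#' @param pseudo_count pseudo-count p added to both observed and reference
#'   counts (default 1).
#' @return matrix of energies with the same shape.
#' @export
inverse_boltzmann <- function(obs, pseudo_count = 1) {
  obs <- as.matrix(obs)
  total <- sum(obs)
  if (total == 0) return(matrix(0, nrow(obs), ncol(obs),
                                dimnames = dimnames(obs)))
  ref_dist <- colSums(obs) / total
  ref <- outer(rowSums(obs), ref_dist)
  -log((obs + pseudo_count) / (ref + pseudo_count))
}

aa_index <- function(a) {
  k <- match(a, AA20)
  k[is.na(k)] <- match("A", AA20)  # unknown residues scored as ALA
  k
}

env_cb_or_ca <- function(cb_row, ca_row) {
  if (is.na(cb_row[1])) ca_row else cb_row
}

# distance bin index for breaks seq(lo, hi, by = width); NA outside
dist_bin_index <- function(d, lo, hi, width) {
  k <- floor((d - lo) / width) + 1L
  k[d < lo | d >= hi] <- NA_integer_
  k
}

torsion_bin_index <- function(angle_rad, width_deg = 30) {
  deg <- angle_rad * 180 / pi
  k <- floor((deg + 180) / width_deg) + 1L
  nb <- as.integer(360 / width_deg)
  pmin(pmax(k, 1L), nb)
}

#' Train the backbone statistical potentials from a StructureDB
#'
#' Produces four tables: a CB-CB distance potential (`cbeta`), a CA-CA
#' distance x CB-direction orientation potential (`reduced`), a per-residue
#' phi/psi torsion potential (`torsion`) and a CB packing-count potential
#' (`cb_packing`). See the package vignette for the exact binning.
#'
#' @param db a `structure_db` with at least one chain.
#' @param cbeta_breaks distance binning for the cbeta/reduced potentials:
#'   `c(lo, hi, width)` in Angstrom (default 1 to 15 by 1).
#' @param seq_sep_min minimum sequence separation for pair statistics
#'   (default 4).
#' @param torsion_bin_deg phi/psi bin width in degrees (default 30).
#' @param packing_cutoff CB packing sphere radius in Angstrom (default 10).
#' @param packing_max maximum neighbour count bin (default 30).
#' @param pseudo_count inverse-Boltzmann pseudo-count (default 1).
#' @return list with elements `cbeta`, `reduced` (class `pair_potential`),
#'   `torsion` (class `torsion_potential`) and `cb_packing` (class
#'   `packing_potential`).
#' @export
train_potentials <- function(db, cbeta_breaks = c(1, 15, 1), seq_sep_min = 4,
                             torsion_bin_deg = 30, packing_cutoff = 10,
                             packing_max = 30, pseudo_count = 1) {
  stopifnot(inherits(db, "structure_db"))
  if (length(db$chains) == 0) stop("cannot train potentials from an empty db")
  lo <- cbeta_breaks[1]; hi <- cbeta_breaks[2]; width <- cbeta_breaks[3]
  nb_dist <- as.integer((hi - lo) / width)
  nb_tor <- as.integer(360 / torsion_bin_deg)
  n_aa <- length(AA20)

  pair_ctx <- function(i, j) (min(i, j) - 1L) * n_aa + max(i, j)
  cbeta_obs <- matrix(0, n_aa * n_aa, nb_dist)
  reduced_obs <- matrix(0, n_aa * n_aa, nb_dist * 4L)
  torsion_obs <- matrix(0, n_aa, nb_tor * nb_tor)
  packing_obs <- matrix(0, n_aa, packing_max + 1L)

  for (ch in db$chains) {
    L <- nchar(ch$sequence)
    aa <- aa_index(strsplit(ch$sequence, "")[[1]])
    cb <- matrix(NA_real_, L, 3)
    for (i in seq_len(L)) {
      cb[i, ] <- reconstruct_cb(ch$n[i, ], ch$ca[i, ], ch$c[i, ])
    }
    # torsions
    for (i in seq_len(L)) {
      if (!is.na(ch$phi[i]) && !is.na(ch$psi[i])) {
        bin <- (torsion_bin_index(ch$phi[i], torsion_bin_deg) - 1L) * nb_tor +
          torsion_bin_index(ch$psi[i], torsion_bin_deg)
        torsion_obs[aa[i], bin] <- torsion_obs[aa[i], bin] + 1
      }
    }
    # packing counts
    d2cb <- cross_dist2(cb, cb)
    for (i in seq_len(L)) {
      cnt <- sum(d2cb[i, -i] <= packing_cutoff^2)
      cnt <- min(cnt, packing_max)
      packing_obs[aa[i], cnt + 1L] <- packing_obs[aa[i], cnt + 1L] + 1
    }
    # pair statistics
    if (L > seq_sep_min) {
      for (i in seq_len(L - seq_sep_min)) {
        for (j in (i + seq_sep_min):L) {
          ctx <- pair_ctx(aa[i], aa[j])
          dcb <- sqrt(sum((cb[i, ] - cb[j, ])^2))
          kb <- dist_bin_index(dcb, lo, hi, width)
          if (!is.na(kb)) cbeta_obs[ctx, kb] <- cbeta_obs[ctx, kb] + 1
          dca <- sqrt(sum((ch$ca[i, ] - ch$ca[j, ])^2))
          kb2 <- dist_bin_index(dca, lo, hi, width)
          if (!is.na(kb2)) {
            vi <- cb[i, ] - ch$ca[i, ]
            vj <- cb[j, ] - ch$ca[j, ]
            ang <- acos(max(-1, min(1, sum(vi * vj) /
                                      (vnorm(vi) * vnorm(vj)))))
            ka <- min(floor(ang / (pi / 4)) + 1L, 4L)
            col <- (kb2 - 1L) * 4L + ka
            reduced_obs[ctx, col] <- reduced_obs[ctx, col] + 1
          }
        }
      }
    }
  }

  meta <- list(pseudo_count = pseudo_count,
               reference = "context-free pooled bin distribution")
  pot <- list(
    cbeta = structure(list(kind = "cbeta",
                           breaks = c(lo, hi, width),
                           seq_sep_min = seq_sep_min,
                           table = inverse_boltzmann(cbeta_obs, pseudo_count),
                           counts = sum(cbeta_obs), meta = meta),
                      class = "pair_potential"),
    reduced = structure(list(kind = "reduced",
                             breaks = c(lo, hi, width), angle_bins = 4L,
                             seq_sep_min = seq_sep_min,
                             table = inverse_boltzmann(reduced_obs,
                                                       pseudo_count),
                             counts = sum(reduced_obs), meta = meta),
                        class = "pair_potential"),
    torsion = structure(list(bin_deg = torsion_bin_deg,
                             table = inverse_boltzmann(torsion_obs,
                                                       pseudo_count),
                             counts = sum(torsion_obs), meta = meta),
                        class = "torsion_potential"),
    cb_packing = structure(list(cutoff = packing_cutoff,
                                max_count = packing_max,
                                table = inverse_boltzmann(packing_obs,
                                                          pseudo_count),
                                counts = sum(packing_obs), meta = meta),
                           class = "packing_potential"))
  pot
}

#' Torsion potential lookup
#' @param pot a `torsion_potential`.
#' @param aa one-letter residue code.
#' @param phi,psi torsions in radians.
#' @return pseudo-energy (lower is better).
#' @export
torsion_energy <- function(pot, aa, phi, psi) {
  nb <- as.integer(360 / pot$bin_deg)
  bin <- (torsion_bin_index(phi, pot$bin_deg) - 1L) * nb +
    torsion_bin_index(psi, pot$bin_deg)
  pot$table[aa_index(aa), bin]
}

#' Sample phi/psi from a torsion potential
#'
#' Bins are drawn with probability proportional to exp(-E), then a uniform
#' angle is drawn within the bin. Used by the Monte Carlo loop sampler.
#'
#' @param pot a `torsion_potential`.
#' @param aa one-letter residue code.
#' @return length-2 numeric c(phi, psi) in radians.
#' @export
torsion_sample <- function(pot, aa) {
  nb <- as.integer(360 / pot$bin_deg)
  e <- pot$table[aa_index(aa), ]
  p <- exp(-e)
  p <- p / sum(p)
  bin <- sample.int(nb * nb, 1, prob = p) - 1L
  phi_bin <- bin %/% nb
  psi_bin <- bin %% nb
  w <- pot$bin_deg * pi / 180
  c(-pi + (phi_bin + stats::runif(1)) * w,
    -pi + (psi_bin + stats::runif(1)) * w)
}

pair_energy_lookup <- function(pot, aa_i, aa_j, d, ang = NULL) {
  n_aa <- length(AA20)
  i <- aa_index(aa_i)
  j <- aa_index(aa_j)
  ctx <- (min(i, j) - 1L) * n_aa + max(i, j)
  kb <- dist_bin_index(d, pot$breaks[1], pot$breaks[2], pot$breaks[3])
  if (is.na(kb)) return(0)
  if (pot$kind == "cbeta") {
    pot$table[ctx, kb]
  } else {
    ka <- min(floor(ang / (pi / 4)) + 1L, 4L)
    pot$table[ctx, (kb - 1L) * 4L + ka]
  }
}
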
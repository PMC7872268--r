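# Backbone scorers evaluated against a scoring environment. All scorers
# follow the "lower is better" convention and are normalized per segment
# residue, so segments of different lengths are comparable during gap
# elongation. Internals are vectorized: distance work is done on whole
# coordinate matrices, the spatial hash backs the neighbour queries.

#' Piecewise-linear steric repulsion
#'
#' Zero beyond the summed radii R, a ceiling of 10 below 0.8254 * R and
#' linear in between.
#'
#' @param d distance(s) in Angstrom.
#' @param R summed hard-sphere radii.
#' @return penalty value(s) in `[0, 10]`.
#' @export
clash_penalty <- function(d, R) {
  lower <- 0.8254 * R
  out <- 10 * (R - d) / (R - lower)
  out[d >= R] <- 0
  out[d <= lower] <- 10
  out
}

# adjacency exclusion for backbone clash pairs: returns TRUE if the pair of
# atoms (kind_i of residue i, kind_j of residue j) is a bonded/1-3/1-4
# peptide-unit contact that must not be counted
clash_excluded <- function(i, kind_i, j, kind_j) {
  if (i == j) return(TRUE)
  if (abs(i - j) != 1) return(FALSE)
  if (i > j) {
    tmp <- i; i <- j; j <- tmp
    tmp <- kind_i; kind_i <- kind_j; kind_j <- tmp
  }
  (kind_i %in% c("c", "o") && kind_j %in% c("n", "ca", "cb", "c", "o")) ||
    (kind_i %in% c("ca", "cb") && kind_j == "n")
}

ENV_KIND_ELEMENT <- c(n = "N", ca = "C", c = "C", o = "O", cb = "C")

# CB matrix with CA fallback over given residue indices
env_cb_matrix <- function(env, idx) {
  cb <- env$coords$cb[idx, , drop = FALSE]
  miss <- is.na(cb[, 1])
  cb[miss, ] <- env$coords$ca[idx[miss], , drop = FALSE]
  cb
}

# vectorized pair-potential lookup for paired aa/distance (+angle) vectors
pair_energy_vec <- function(pot, aa_i, aa_j, d, ang = NULL) {
  n_aa <- length(AA20)
  i <- aa_index(aa_i)
  j <- aa_index(aa_j)
  ctx <- (pmin(i, j) - 1L) * n_aa + pmax(i, j)
  kb <- dist_bin_index(d, pot$breaks[1], pot$breaks[2], pot$breaks[3])
  ok <- !is.na(kb)
  out <- numeric(length(d))
  if (!any(ok)) return(out)
  if (pot$kind == "cbeta") {
    out[ok] <- pot$table[cbind(ctx[ok], kb[ok])]
  } else {
    ka <- pmin(floor(ang / (pi / 4)) + 1L, 4L)
    out[ok] <- pot$table[cbind(ctx[ok], (kb[ok] - 1L) * 4L + ka[ok])]
  }
  out
}

# pair mask: rows = segment residues (indices `range`), cols = set residues;
# TRUE where the pair must be counted (once within the segment)
segment_pair_mask <- function(range, set_idx, in_seg, seq_sep_min) {
  sep_ok <- abs(outer(range, set_idx, `-`)) >= seq_sep_min
  dup <- outer(range, set_idx, function(i, j) in_seg[j] & j <= i)
  sep_ok & !dup
}

#' Score a model segment
#'
#' Evaluates one scorer over the residues in `range` against the rest of the
#' environment; the result is normalized by the segment length. Pairs inside
#' the segment are counted once; pairs between the segment and external set
#' residues are included.
#'
#' @param env a `scoring_env` with the segment residues set.
#' @param range integer residue indices of the segment.
#' @param kind one of `"cbeta"`, `"cb_packing"`, `"clash"`, `"hbond"`,
#'   `"torsion"`, `"reduced"`, `"constraint"`.
#' @param tables potential tables from [train_potentials()] (required for
#'   the statistical kinds).
#' @param params list of extra parameters: `radii` (clash radii table),
#'   `constraints` for the constraint scorer (list of
#'   `list(i, j, atoms = "ca"|"cb", fn = function(d) ...)`).
#' @return numeric score (lower is better), per-residue normalized.
#' @export
score_segment <- function(env, range, kind, tables = NULL, params = list()) {
  stopifnot(inherits(env, "scoring_env"))
  if (!all(env$set[range])) stop("segment contains unset residues")
  nseg <- length(range)
  in_seg <- rep(FALSE, length(env$seq))
  in_seg[range] <- TRUE
  set_idx <- which(env$set)

  total <- switch(kind,
    cbeta = {
      pot <- tables$cbeta
      cb_seg <- env_cb_matrix(env, range)
      cb_set <- env_cb_matrix(env, set_idx)
      mask <- segment_pair_mask(range, set_idx, in_seg, pot$seq_sep_min)
      d <- sqrt(pmax(cross_dist2(cb_seg, cb_set), 0))
      pr <- which(mask, arr.ind = TRUE)
      sum(pair_energy_vec(pot, env$seq[range[pr[, 1]]],
                          env$seq[set_idx[pr[, 2]]], d[pr]))
    },
    reduced = {
      pot <- tables$reduced
      ca_seg <- env$coords$ca[range, , drop = FALSE]
      ca_set <- env$coords$ca[set_idx, , drop = FALSE]
      v_seg <- env_cb_matrix(env, range) - ca_seg
      v_set <- env_cb_matrix(env, set_idx) - ca_set
      v_seg <- v_seg / sqrt(rowSums(v_seg^2))
      v_set <- v_set / sqrt(rowSums(v_set^2))
      mask <- segment_pair_mask(range, set_idx, in_seg, pot$seq_sep_min)
      d <- sqrt(pmax(cross_dist2(ca_seg, ca_set), 0))
      cosang <- pmin(pmax(tcrossprod(v_seg, v_set), -1), 1)
      pr <- which(mask, arr.ind = TRUE)
      sum(pair_energy_vec(pot, env$seq[range[pr[, 1]]],
                          env$seq[set_idx[pr[, 2]]], d[pr],
                          acos(cosang[pr])))
    },
    cb_packing = {
      pot <- tables$cb_packing
      cb_seg <- env_cb_matrix(env, range)
      cb_set <- env_cb_matrix(env, set_idx)
      d2 <- cross_dist2(cb_seg, cb_set)
      self <- outer(range, set_idx, `==`)
      cnt <- rowSums(d2 <= pot$cutoff^2 & !self)
      cnt <- pmin(cnt, pot$max_count)
      sum(pot$table[cbind(aa_index(env$seq[range]), cnt + 1L)])
    },
    torsion = {
      pot <- tables$torsion
      s <- 0
      for (i in range) {
        tp <- env_phi_psi(env, i)
        if (any(is.na(tp))) next
        s <- s + torsion_energy(pot, env$seq[i], tp[1], tp[2])
      }
      s
    },
    clash = {
      radii <- if (!is.null(params$radii)) params$radii else CLASH_RADII
      at_seg <- env_atoms_of(env, range)
      at_set <- env_atoms_of(env, set_idx)
      if (nrow(at_seg$pos) == 0 || nrow(at_set$pos) == 0) 0 else {
        d <- sqrt(pmax(cross_dist2(at_seg$pos, at_set$pos), 0))
        R <- outer(radii[ENV_KIND_ELEMENT[at_seg$kind]],
                   radii[ENV_KIND_ELEMENT[at_set$kind]], `+`)
        hit <- which(d < R, arr.ind = TRUE)
        s <- 0
        for (h in seq_len(nrow(hit))) {
          a <- hit[h, 1]
          b <- hit[h, 2]
          i <- at_seg$res[a]
          j <- at_set$res[b]
          if (in_seg[j] && j <= i) next
          if (clash_excluded(i, at_seg$kind[a], j, at_set$kind[b])) next
          s <- s + clash_penalty(d[hit[h, , drop = FALSE]], R[hit[h, ,
                                                                  drop = FALSE]])
        }
        s
      }
    },
    hbond = {
      E <- env_hbond_matrix(env, focus = range)
      bonds <- !is.na(E) & E < -0.5
      if (!any(bonds)) 0 else {
        idx <- which(bonds, arr.ind = TRUE)
        keep <- in_seg[idx[, 1]] | in_seg[idx[, 2]]
        sum(E[idx[keep, , drop = FALSE]])
      }
    },
    constraint = {
      cons <- params$constraints
      if (is.null(cons)) stop("constraint scorer needs params$constraints")
      s <- 0
      for (cc in cons) {
        if (!(in_seg[cc$i] || in_seg[cc$j])) next
        if (!(env$set[cc$i] && env$set[cc$j])) next
        pa <- if (identical(cc$atoms, "cb")) env_cb_matrix(env, cc$i)[1, ]
              else env$coords$ca[cc$i, ]
        pb <- if (identical(cc$atoms, "cb")) env_cb_matrix(env, cc$j)[1, ]
              else env$coords$ca[cc$j, ]
        s <- s + cc$fn(sqrt(sum((pa - pb)^2)))
      }
      s
    },
    stop("unknown scorer kind: ", kind)
  )
  total / nseg
}

# flat atom table (pos/res/kind) over the given residues
env_atoms_of <- function(env, idx) {
  pos <- NULL
  res <- integer(0)
  kind <- character(0)
  for (a in ENV_ATOMS) {
    m <- env$coords[[a]][idx, , drop = FALSE]
    ok <- !is.na(m[, 1])
    pos <- rbind(pos, m[ok, , drop = FALSE])
    res <- c(res, idx[ok])
    kind <- c(kind, rep(a, sum(ok)))
  }
  list(pos = pos, res = res, kind = kind)
}

# Kabsch-Sander energies on the set part of the environment. With `focus`,
# only pairs involving a focus residue are computed (others stay NA).
env_hbond_matrix <- function(env, focus = NULL) {
  nres <- length(env$seq)
  E <- matrix(NA_real_, nres, nres)
  q <- 0.084 * 332
  set_idx <- which(env$set)
  if (length(set_idx) == 0) return(E)
  # amide H for set residues with a set predecessor
  h <- matrix(NA_real_, nres, 3)
  for (i in set_idx) {
    if (i == 1 || env$seq[i] == "P") next
    if (!env$set[i - 1]) next
    d <- unitv(unitv(env$coords$n[i, ] - env$coords$c[i - 1, ]) +
               unitv(env$coords$n[i, ] - env$coords$ca[i, ]))
    h[i, ] <- env$coords$n[i, ] + d
  }
  donors <- set_idx[!is.na(h[set_idx, 1])]
  acceptors <- set_idx
  if (length(donors) == 0) return(E)
  in_focus <- rep(is.null(focus), nres)
  in_focus[focus] <- TRUE
  r_on <- sqrt(pmax(cross_dist2(env$coords$n[donors, , drop = FALSE],
                                env$coords$o[acceptors, , drop = FALSE]), 0))
  r_ch <- sqrt(pmax(cross_dist2(h[donors, , drop = FALSE],
                                env$coords$c[acceptors, , drop = FALSE]), 0))
  r_oh <- sqrt(pmax(cross_dist2(h[donors, , drop = FALSE],
                                env$coords$o[acceptors, , drop = FALSE]), 0))
  r_cn <- sqrt(pmax(cross_dist2(env$coords$n[donors, , drop = FALSE],
                                env$coords$c[acceptors, , drop = FALSE]), 0))
  val <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  val[pmin(r_on, r_ch, r_oh, r_cn) < 0.5] <- -9.9
  sep_ok <- abs(outer(donors, acceptors, `-`)) >= 2
  rel <- outer(in_focus[donors], in_focus[acceptors], `|`)
  use <- sep_ok & rel & r_on < 7  # distance gate: beyond 7 A never < -0.5
  E[cbind(donors[row(use)[use]], acceptors[col(use)[use]])] <- val[use]
  E
}

#' Linear combination of named scores
#' @param scores named numeric vector or list of score values.
#' @param weights named numeric vector; every weighted name must be present
#'   in `scores`.
#' @return weighted sum.
#' @export
combine_scores <- function(scores, weights) {
  scores <- unlist(scores)
  missing <- setdiff(names(weights), names(scores))
  if (length(missing) > 0) {
    stop("missing score(s): ", paste(missing, collapse = ", "))
  }
  sum(weights * scores[names(weights)])
}

#' Fit linear selection weights from scored decoys
#'
#' Least-squares regression of loop CA-RMSD on the score vectors (intercept
#' fitted then discarded). Rank-deficient designs fall back to the
#' minimum-norm solution with a warning.
#'
#' @param score_matrix n x p matrix of decoy scores (columns named).
#' @param rmsd length-n CA-RMSD labels.
#' @return named weight vector of length p.
#' @export
fit_weights <- function(score_matrix, rmsd) {
  score_matrix <- as.matrix(score_matrix)
  if (nrow(score_matrix) < 10) stop("need at least 10 decoys")
  if (length(unique(rmsd)) < 2) stop("need at least 2 distinct RMSD labels")
  X <- cbind(1, score_matrix)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient design; returning minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rmsd)) / sv$d[pos])
  } else {
    beta <- qr.coef(qr_x, rmsd)
  }
  w <- as.numeric(beta)[-1]
  names(w) <- colnames(score_matrix)
  w
}
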
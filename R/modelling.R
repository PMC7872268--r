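# Modelling pipeline: raw model construction from a target-template
# alignment, deletion handling, gap elongation, database and Monte Carlo
# loop filling, stereochemistry regularization and the full build pipeline.
# Scope: single-chain targets.

#' @export
print.modelling_handle <- function(x, ...) {
  cat("<modelling_handle> ", length(x$target_seq), " residues, ",
      sum(x$present), " built, ", length(x$gaps), " gap(s)\n", sep = "")
  invisible(x)
}

mh_anchor <- function(mh, i) {
  rbind(mh$n[i, ], mh$ca[i, ], mh$c[i, ])
}

mh_segment_bb <- function(mh, idx) {
  new_backbone(mh$target_seq[idx], mh$n[idx, , drop = FALSE],
               mh$ca[idx, , drop = FALSE], mh$c[idx, , drop = FALSE],
               mh$o[idx, , drop = FALSE], mh$cb[idx, , drop = FALSE])
}

mh_write_segment <- function(mh, bb, idx) {
  mh$n[idx, ] <- bb$n
  mh$ca[idx, ] <- bb$ca
  mh$c[idx, ] <- bb$c
  mh$o[idx, ] <- bb$o
  mh$cb[idx, ] <- bb$cb
  mh$present[idx] <- TRUE
  # a remodelled backbone invalidates any template sidechain there
  for (i in idx) mh$sidechains[i] <- list(NULL)
  mh
}

mh_env <- function(mh, exclude = integer(0)) {
  env <- env_new(mh$target_seq)
  idx <- setdiff(which(mh$present), exclude)
  if (length(idx) > 0) {
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    for (r in runs) env <- env_set(env, mh_segment_bb(mh, r), r)
  }
  env
}

#' Build the raw model from an attached alignment
#'
#' Row 1 is the target, row 2 the template (attached with [attach_view()]).
#' Aligned columns transfer the template backbone; the residue is renamed to
#' the target amino acid and the template sidechain is kept only on identical
#' residues. Target-only columns become insertion gaps, template-only
#' columns deletion gaps, and terminal target overhangs terminal gaps.
#'
#' @param aln an `alignment` with >= 2 rows and row 2 attached.
#' @return object of class `modelling_handle`.
#' @export
build_raw_model <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  att <- aln$attachments[[2]]
  if (is.null(att)) stop("template row has no attached structure")
  tpl_chain <- chain_by_id(att$structure, att$chain)
  tpl_bb <- backbone_from_chain(att$structure, att$chain)
  tpl_ss <- strsplit(assign_ss(tpl_bb), "")[[1]]

  t_chars <- strsplit(aln$rows[[1]], "")[[1]]
  p_chars <- strsplit(aln$rows[[2]], "")[[1]]
  nt <- sum(t_chars != "-")
  if (nt == 0) stop("empty target sequence")

  mh <- structure(list(
    target_seq = t_chars[t_chars != "-"],
    chain_id = att$chain,
    n = matrix(NA_real_, nt, 3), ca = matrix(NA_real_, nt, 3),
    c = matrix(NA_real_, nt, 3), o = matrix(NA_real_, nt, 3),
    cb = matrix(NA_real_, nt, 3),
    present = rep(FALSE, nt),
    sidechains = vector("list", nt),
    template_ss = rep(NA_character_, nt),
    gaps = list(), trimmed = integer(0)),
    class = "modelling_handle")

  ti <- 0L
  deletion_after <- integer(0)  # target positions followed by a deletion
  for (col in seq_along(t_chars)) {
    t_gap <- t_chars[col] == "-"
    p_res <- att$col_map[col]
    if (!t_gap) ti <- ti + 1L
    if (!t_gap && !is.na(p_res)) {
      res <- tpl_chain$residues[[p_res]]
      mh$n[ti, ] <- tpl_bb$n[p_res, ]
      mh$ca[ti, ] <- tpl_bb$ca[p_res, ]
      mh$c[ti, ] <- tpl_bb$c[p_res, ]
      mh$o[ti, ] <- tpl_bb$o[p_res, ]
      mh$present[ti] <- TRUE
      mh$template_ss[ti] <- tpl_ss[p_res]
      aa_t <- mh$target_seq[ti]
      if (aa_t != "G") {
        mh$cb[ti, ] <- if (!is.na(tpl_bb$cb[p_res, 1])) tpl_bb$cb[p_res, ]
                       else reconstruct_cb(tpl_bb$n[p_res, ],
                                           tpl_bb$ca[p_res, ],
                                           tpl_bb$c[p_res, ])
      }
      if (aa_t == res$one_letter && residue_is_complete(res)) {
        extra <- res$atoms[!rownames(res$atoms) %in%
                             c(BACKBONE_ATOMS, "CB"), , drop = FALSE]
        if (nrow(extra) > 0) mh$sidechains[[ti]] <- extra
      }
    } else if (t_gap && !is.na(p_res)) {
      if (ti >= 1L) deletion_after <- union(deletion_after, ti)
    }
  }

  # insertion / terminal gaps from unbuilt runs
  unbuilt <- which(!mh$present)
  if (length(unbuilt) > 0) {
    runs <- split(unbuilt, cumsum(c(1, diff(unbuilt) != 1)))
    for (r in runs) {
      mh$gaps[[length(mh$gaps) + 1L]] <- list(
        before = min(r) - 1L, after = max(r) + 1L,
        seq = paste(mh$target_seq[r], collapse = ""))
    }
  }
  # deletion gaps (skip those adjacent to an unbuilt run: subsumed)
  for (d in deletion_after) {
    if (d >= 1L && d < nt && mh$present[d] && mh$present[d + 1L]) {
      mh$gaps[[length(mh$gaps) + 1L]] <- list(before = d, after = d + 1L,
                                              seq = "")
    }
  }
  if (length(mh$gaps) > 0) {
    ord <- order(vapply(mh$gaps, `[[`, 0L, "before"))
    mh$gaps <- mh$gaps[ord]
  }
  mh
}

peptide_bonds_ok <- function(bb) {
  nres <- length(bb$seq)
  if (nres < 2) return(TRUE)
  for (i in seq_len(nres - 1)) {
    d <- vnorm(bb$n[i + 1, ] - bb$c[i, ])
    if (d < 1.2 || d > 1.5) return(FALSE)
  }
  TRUE
}

#' Resolve small deletions by relaxing neighbouring residues
#'
#' For every pure-deletion gap, up to two built residues on each side form a
#' mini-loop that is re-bridged with CCD. The closure is accepted (and the
#' gap removed) only if the segment is clash-free and all peptide bonds stay
#' within 1.2-1.5 Angstrom; otherwise the gap is retained and later
#' treated like an insertion.
#'
#' @param mh a `modelling_handle`.
#' @param cfg a [pipeline_config()].
#' @return updated handle.
#' @export
handle_deletions <- function(mh, cfg = pipeline_config()) {
  keep <- list()
  for (gap in mh$gaps) {
    if (nchar(gap$seq) > 0) {
      keep[[length(keep) + 1L]] <- gap
      next
    }
    nt <- length(mh$target_seq)
    p0 <- gap$before - 2L
    p1 <- gap$after + 2L
    ok_span <- p0 >= 1L && p1 <= nt && all(mh$present[p0:p1])
    resolved <- FALSE
    if (ok_span) {
      # rebuild the mini-loop from its own torsions with ideal bond
      # lengths: this restores backbone continuity across the deletion
      # (the copied template coordinates leave a long C-N bond) and CCD
      # then drives the last residue back onto the C-stem
      meas <- mh_segment_bb(mh, p0:p1)
      phi0 <- meas$phi
      psi0 <- meas$psi
      phi0[is.na(phi0)] <- -120 * pi / 180
      psi0[is.na(psi0)] <- 140 * pi / 180
      for (attempt in 0:9) {  # deterministic jittered restarts
        set.seed(1000L * gap$before + attempt)
        jit <- if (attempt == 0) 0 else 25 * pi / 180
        phi <- phi0 + stats::rnorm(length(phi0), 0, jit)
        psi <- psi0 + stats::rnorm(length(psi0), 0, jit)
        loop <- backbone_from_torsions(paste(meas$seq, collapse = ""),
                                       phi, psi)
        res <- ccd_close(loop, mh_anchor(mh, p0), mh_anchor(mh, p1),
                         max_iter = 2L * cfg$ccd_max_iter,
                         tol = cfg$ccd_tol)
        if (!res$converged || !peptide_bonds_ok(res$loop)) next
        interior <- (p0 + 1L):(p1 - 1L)
        cand <- bb_subset(res$loop, 2:(length(res$loop$seq) - 1L))
        mh2 <- mh_write_segment(mh, cand, interior)
        env <- mh_env(mh2)
        clash <- score_segment(env, interior, "clash")
        # closing bond onto the fixed C-stem must stay in range
        dbond <- vnorm(mh2$n[p1, ] - mh2$c[p1 - 1L, ])
        if (clash == 0 && dbond >= 1.2 && dbond <= 1.5) {
          mh <- mh2
          resolved <- TRUE
          break
        }
      }
    }
    if (!resolved) keep[[length(keep) + 1L]] <- gap
  }
  mh$gaps <- keep
  mh
}

#' Enumerate gap elongations
#'
#' Converts 0..k built flanking residues on either side into loop, producing
#' candidate extents ordered by total modelled length, then preferring to
#' consume flanking residues whose template secondary structure is coil,
#' then N-side first.
#'
#' @param gap one gap record of a `modelling_handle`.
#' @param mh the handle.
#' @param max_length cap on the modelled loop length.
#' @return list of `list(n_stem, c_stem, length)` (possibly empty).
#' @export
extend_gap <- function(gap, mh, max_length) {
  nt <- length(mh$target_seq)
  base <- gap$after - gap$before - 1L
  exts <- list()
  for (k_n in 0:(max_length)) {
    n_stem <- gap$before - k_n
    if (n_stem < 1L || !all(mh$present[n_stem:gap$before])) break
    for (k_c in 0:(max_length)) {
      c_stem <- gap$after + k_c
      if (c_stem > nt || !all(mh$present[gap$after:c_stem])) break
      total <- base + k_n + k_c
      if (total < 1L) next
      if (total > max_length) break
      consumed <- c(if (k_n > 0) (n_stem + 1L):gap$before else integer(0),
                    if (k_c > 0) gap$after:(c_stem - 1L) else integer(0))
      ss <- mh$template_ss[consumed]
      helix_cost <- sum(!is.na(ss) & ss %in% c("H", "E"))
      exts[[length(exts) + 1L]] <- list(n_stem = n_stem, c_stem = c_stem,
                                        length = total,
                                        helix_cost = helix_cost, k_n = k_n)
    }
  }
  if (length(exts) == 0) return(list())
  ord <- order(vapply(exts, `[[`, 0L, "length"),
               vapply(exts, `[[`, 0L, "helix_cost"),
               -vapply(exts, `[[`, 0L, "k_n"))
  lapply(exts[ord], function(e) e[c("n_stem", "c_stem", "length")])
}

score_loop_candidate <- function(env_base, loop, n_stem, c_stem, tables,
                                 weights, stem_rmsd) {
  interior <- (n_stem + 1L):(c_stem - 1L)
  inner_bb <- bb_subset(loop, 2:(length(loop$seq) - 1L))
  env <- env_set(env_base, inner_bb, interior)
  kinds <- c("cbeta", "cb_packing", "clash", "hbond", "torsion", "reduced")
  scores <- vapply(kinds, function(k) {
    score_segment(env, interior, k, tables)
  }, 0)
  scores <- c(scores, stem_rmsd = stem_rmsd)
  combine_scores(scores, weights[names(weights) %in% names(scores)])
}

#' Fill gaps with database loop candidates
#'
#' For every gap, elongations are enumerated and the FragDB queried at each
#' extent's stem geometry. Candidates are fitted with CCD, scored with the
#' backbone scorer set plus the pre-CCD stem RMSD, linearly combined, and
#' the best candidate committed. Unresolved gaps remain for the Monte Carlo
#' fallback.
#'
#' @param mh a `modelling_handle`.
#' @param fdb a `frag_db`.
#' @param sdb the `structure_db` the FragDB indexes into.
#' @param tables potentials from [train_potentials()].
#' @param cfg a [pipeline_config()].
#' @return updated handle.
#' @export
fill_loops_by_database <- function(mh, fdb, sdb, tables,
                                   cfg = pipeline_config()) {
  remaining <- list()
  for (gap in mh$gaps) {
    if (gap$before < 1L || gap$after > length(mh$target_seq)) {
      remaining[[length(remaining) + 1L]] <- gap  # terminal: MC only
      next
    }
    exts <- extend_gap(gap, mh, cfg$max_loop_length)
    best <- NULL
    n_scored <- 0L
    # widen the geometric search until candidates appear
    for (eb in cfg$extra_bins:cfg$max_extra_bins) {
    for (ext in exts) {
      span <- ext$n_stem:ext$c_stem
      interior <- span[-c(1, length(span))]
      env_base <- mh_env(mh, exclude = interior)
      g <- stem_geometry(mh_anchor(mh, ext$n_stem),
                         mh_anchor(mh, ext$c_stem), ext$length)
      addrs <- fragdb_query(fdb, g, eb)
      for (addr in addrs) {
        frag <- fragment_with_stems(sdb, addr$chain_index, addr$offset,
                                    addr$length)
        # mutate to the target sequence (CB rebuilt for the new residues)
        cand <- new_backbone(mh$target_seq[span], frag$n, frag$ca, frag$c,
                             frag$o)
        stem_idx <- c(1L, length(span))
        A <- rbind(cand$n[stem_idx, ], cand$ca[stem_idx, ],
                   cand$c[stem_idx, ])
        B <- rbind(mh$n[c(ext$n_stem, ext$c_stem), ],
                   mh$ca[c(ext$n_stem, ext$c_stem), ],
                   mh$c[c(ext$n_stem, ext$c_stem), ])
        fit <- kabsch(A, B)
        stem_rmsd <- fit$rmsd
        cand <- transform_backbone(cand, fit$rotation, fit$translation)
        res <- ccd_close(cand, mh_anchor(mh, ext$n_stem),
                         mh_anchor(mh, ext$c_stem),
                         max_iter = cfg$ccd_max_iter, tol = cfg$ccd_tol)
        if (!res$converged) next
        sc <- score_loop_candidate(env_base, res$loop, ext$n_stem,
                                   ext$c_stem, tables, cfg$weights,
                                   stem_rmsd)
        n_scored <- n_scored + 1L
        if (is.null(best) || sc < best$score) {
          best <- list(score = sc, loop = res$loop, n_stem = ext$n_stem,
                       c_stem = ext$c_stem)
        }
        if (n_scored >= cfg$candidates_per_gap) break
      }
      if (n_scored >= cfg$candidates_per_gap) break
    }
    if (n_scored > 0) break
    }
    if (!is.null(best)) {
      interior <- (best$n_stem + 1L):(best$c_stem - 1L)
      inner <- bb_subset(best$loop, 2:(length(best$loop$seq) - 1L))
      mh <- mh_write_segment(mh, inner, interior)
    } else {
      remaining[[length(remaining) + 1L]] <- gap
    }
  }
  mh$gaps <- remaining
  mh
}

sample_loop_torsions <- function(seq1, tables) {
  nres <- length(seq1)
  phi <- psi <- numeric(nres)
  for (i in seq_len(nres)) {
    tp <- torsion_sample(tables$torsion, seq1[i])
    phi[i] <- tp[1]
    psi[i] <- tp[2]
  }
  list(phi = phi, psi = psi)
}

mc_combined_score <- function(env_base, loop, n_stem, c_stem, tables,
                              weights, closure) {
  score_loop_candidate(env_base, loop, n_stem, c_stem, tables, weights,
                       stem_rmsd = closure)
}

fill_terminal_gap <- function(mh, gap, tables, cfg) {
  nt <- length(mh$target_seq)
  n_term <- gap$before == 0L
  overhang <- (gap$before + 1L):(gap$after - 1L)
  if (length(overhang) > cfg$terminal_max) {
    warning("terminal overhang of ", length(overhang),
            " residues exceeds terminal_max (", cfg$terminal_max,
            "); trimmed")
    mh$trimmed <- c(mh$trimmed, overhang)
    return(list(mh = mh, resolved = TRUE))
  }
  stem <- if (n_term) gap$after else gap$before
  span <- if (n_term) c(overhang, stem) else c(stem, overhang)
  env_base <- mh_env(mh, exclude = overhang)
  best <- NULL
  n_try <- max(20L, cfg$mc_steps %/% 50L)
  for (k in seq_len(n_try)) {
    tors <- sample_loop_torsions(mh$target_seq[span], tables)
    cand <- backbone_from_torsions(paste(mh$target_seq[span], collapse = ""),
                                   tors$phi, tors$psi)
    stem_row <- if (n_term) length(span) else 1L
    A <- rbind(cand$n[stem_row, ], cand$ca[stem_row, ], cand$c[stem_row, ])
    fit <- kabsch(A, mh_anchor(mh, stem))
    cand <- transform_backbone(cand, fit$rotation, fit$translation)
    inner <- bb_subset(cand, which(span %in% overhang))
    env <- env_set(env_base, inner, overhang)
    sc <- score_segment(env, overhang, "clash") +
      score_segment(env, overhang, "torsion", tables)
    if (is.null(best) || sc < best$score) best <- list(score = sc,
                                                       bb = inner)
  }
  mh <- mh_write_segment(mh, best$bb, overhang)
  list(mh = mh, resolved = TRUE)
}

#' Fill remaining gaps by simulated annealing in torsion space
#'
#' Loops are initialized from per-residue phi/psi draws out of the trained
#' torsion tables, re-closed with CCD after every single-residue move, and
#' accepted by the Metropolis criterion on the combined score (closure RMSD
#' included through the stem term) under geometric cooling. The elongation
#' scheme is applied without the loop-length cap when a gap persistently
#' fails. Terminal overhangs are modelled when short enough, otherwise
#' trimmed with a warning.
#'
#' @param mh a `modelling_handle`.
#' @param tables potentials from [train_potentials()].
#' @param cfg a [pipeline_config()].
#' @param seed RNG seed (reproducible).
#' @return updated handle.
#' @export
fill_loops_monte_carlo <- function(mh, tables, cfg = pipeline_config(),
                                   seed = 1) {
  if (cfg$mc_steps < 1) return(mh)
  set.seed(seed)
  remaining <- list()
  for (gap in mh$gaps) {
    nt <- length(mh$target_seq)
    if (gap$before < 1L || gap$after > nt) {
      res <- fill_terminal_gap(mh, gap, tables, cfg)
      mh <- res$mh
      next
    }
    exts <- extend_gap(gap, mh, max_length = nt)
    resolved <- FALSE
    for (ext in utils::head(exts, 4L)) {
      span <- ext$n_stem:ext$c_stem
      interior <- span[-c(1, length(span))]
      env_base <- mh_env(mh, exclude = interior)
      n_anchor <- mh_anchor(mh, ext$n_stem)
      c_anchor <- mh_anchor(mh, ext$c_stem)
      tors <- sample_loop_torsions(mh$target_seq[span], tables)
      cur <- backbone_from_torsions(paste(mh$target_seq[span],
                                          collapse = ""),
                                    tors$phi, tors$psi)
      closed <- ccd_close(cur, n_anchor, c_anchor,
                          max_iter = cfg$ccd_max_iter, tol = cfg$ccd_tol)
      cur <- closed$loop
      cur_sc <- mc_combined_score(env_base, cur, ext$n_stem, ext$c_stem,
                                  tables, cfg$weights, closed$anchor_rmsd)
      best <- if (closed$converged) list(loop = cur, score = cur_sc)
              else NULL
      Temp <- cfg$mc_T0
      L <- length(span)
      for (s in seq_len(cfg$mc_steps)) {
        i <- sample.int(L, 1)
        tp <- torsion_sample(tables$torsion, cur$seq[i])
        prop <- cur
        if (!is.na(prop$phi[i])) prop <- set_torsion(prop, i, "phi", tp[1])
        if (!is.na(prop$psi[i]) && i < L) {
          prop <- set_torsion(prop, i, "psi", tp[2])
        }
        re <- ccd_close(prop, n_anchor, c_anchor,
                        max_iter = cfg$mc_ccd_iter, tol = cfg$ccd_tol)
        prop_sc <- mc_combined_score(env_base, re$loop, ext$n_stem,
                                     ext$c_stem, tables, cfg$weights,
                                     re$anchor_rmsd)
        dE <- prop_sc - cur_sc
        if (dE <= 0 || stats::runif(1) < exp(-dE / max(Temp, 1e-9))) {
          cur <- re$loop
          cur_sc <- prop_sc
          if (re$converged &&
              (is.null(best) || cur_sc < best$score)) {
            best <- list(loop = cur, score = cur_sc)
          }
        }
        if (s %% L == 0) Temp <- Temp * cfg$mc_cool
      }
      if (!is.null(best)) {
        inner <- bb_subset(best$loop, 2:(L - 1L))
        mh <- mh_write_segment(mh, inner, interior)
        resolved <- TRUE
        break
      }
    }
    if (!resolved) remaining[[length(remaining) + 1L]] <- gap
  }
  mh$gaps <- remaining
  mh
}

#' Convert a modelling handle to a Structure
#'
#' @param mh a `modelling_handle` with all non-trimmed residues built.
#' @return a `structure3d` (template sidechains carried over where kept).
#' @export
mh_to_structure <- function(mh) {
  missing <- which(!mh$present)
  missing <- setdiff(missing, mh$trimmed)
  if (length(missing) > 0) {
    stop("unresolved gap(s) at target position(s): ",
         paste(missing, collapse = ", "))
  }
  residues <- list()
  for (i in which(mh$present)) {
    atoms <- rbind(N = mh$n[i, ], CA = mh$ca[i, ], C = mh$c[i, ],
                   O = mh$o[i, ])
    if (!is.na(mh$cb[i, 1])) atoms <- rbind(atoms, CB = mh$cb[i, ])
    if (!is.null(mh$sidechains[[i]])) {
      atoms <- rbind(atoms, mh$sidechains[[i]])
    }
    residues[[length(residues) + 1L]] <-
      new_residue(i, "", aa_one_to_three(mh$target_seq[i]), atoms)
  }
  new_structure(list(list(id = mh$chain_id, residues = residues)))
}

regularize_penalty <- function(pos, kind, res_id, bonds, geo,
                               radii = CLASH_RADII) {
  P <- 0
  for (b in bonds) {
    d <- vnorm(pos[b$a, ] - pos[b$b, ])
    P <- P + 100 * (d - b$d0)^2
  }
  n_at <- nrow(pos)
  for (a in seq_len(n_at - 1)) {
    for (b in (a + 1):n_at) {
      if (res_id[a] == res_id[b]) next
      if (clash_excluded(res_id[a], kind[a], res_id[b], kind[b])) next
      R <- radii[[ENV_KIND_ELEMENT[[kind[a]]]]] +
        radii[[ENV_KIND_ELEMENT[[kind[b]]]]]
      d <- vnorm(pos[a, ] - pos[b, ])
      if (d < R) P <- P + clash_penalty(d, R)
    }
  }
  P
}

regularize_gradient <- function(pos, kind, res_id, bonds, geo,
                                radii = CLASH_RADII) {
  G <- matrix(0, nrow(pos), 3)
  for (b in bonds) {
    v <- pos[b$a, ] - pos[b$b, ]
    d <- vnorm(v)
    if (d < 1e-9) next
    g <- 200 * (d - b$d0) * v / d
    G[b$a, ] <- G[b$a, ] + g
    G[b$b, ] <- G[b$b, ] - g
  }
  n_at <- nrow(pos)
  for (a in seq_len(n_at - 1)) {
    for (bb_ in (a + 1):n_at) {
      if (res_id[a] == res_id[bb_]) next
      if (clash_excluded(res_id[a], kind[a], res_id[bb_], kind[bb_])) next
      R <- radii[[ENV_KIND_ELEMENT[[kind[a]]]]] +
        radii[[ENV_KIND_ELEMENT[[kind[bb_]]]]]
      v <- pos[a, ] - pos[bb_, ]
      d <- vnorm(v)
      if (d < R && d > 0.8254 * R && d > 1e-9) {
        g <- (-10 / (R * (1 - 0.8254))) * v / d
        G[a, ] <- G[a, ] + g
        G[bb_, ] <- G[bb_, ] - g
      }
    }
  }
  G
}

#' Regularize stereochemistry by restrained steepest descent
#'
#' Minimizes a penalty of harmonic bonded deviations from ideal geometry
#' plus the piecewise-linear clash penalty over backbone + CB atoms. Steps
#' are accepted only when the penalty decreases (backtracking line search);
#' every CA is constrained to stay within 0.5 Angstrom of its input
#' position; sidechain atoms follow their CA rigidly.
#'
#' @param s a `structure3d` with continuous backbone.
#' @param cfg a [pipeline_config()].
#' @return regularized structure.
#' @export
regularize <- function(s, cfg = pipeline_config()) {
  geo <- ideal_geometry()
  for (ci in seq_along(s$chains)) {
    ch <- s$chains[[ci]]
    nres <- length(ch$residues)
    # assemble movable atom table (backbone + CB)
    pos <- NULL
    kind <- character(0)
    res_id <- integer(0)
    slots <- list()
    for (i in seq_len(nres)) {
      at <- ch$residues[[i]]$atoms
      for (nm in c("N", "CA", "C", "O", "CB")) {
        if (nm %in% rownames(at)) {
          pos <- rbind(pos, at[nm, ])
          kind <- c(kind, tolower(nm))
          res_id <- c(res_id, i)
          slots[[length(slots) + 1L]] <- c(i, match(nm, rownames(at)))
        }
      }
    }
    find_atom <- function(i, nm) {
      which(res_id == i & kind == tolower(nm))[1]
    }
    bonds <- list()
    for (i in seq_len(nres)) {
      add <- function(a, b, d0) {
        ia <- find_atom(i, a)
        ib <- find_atom(i, b)
        if (!is.na(ia) && !is.na(ib)) {
          bonds[[length(bonds) + 1L]] <<- list(a = ia, b = ib, d0 = d0)
        }
      }
      add("N", "CA", geo$b_n_ca)
      add("CA", "C", geo$b_ca_c)
      add("C", "O", geo$b_c_o)
      add("CA", "CB", geo$b_ca_cb)
      if (i < nres) {
        ia <- find_atom(i, "C")
        ib <- find_atom(i + 1, "N")
        bonds[[length(bonds) + 1L]] <- list(a = ia, b = ib, d0 = geo$b_c_n)
      }
    }
    pos0 <- pos
    ca_rows <- which(kind == "ca")
    project <- function(x) {
      for (r in ca_rows) {
        dv <- x[r, ] - pos0[r, ]
        d <- vnorm(dv)
        if (d > 0.5) {
          shift <- dv * (0.5 / d) - dv
          rows <- which(res_id == res_id[r])
          x[rows, ] <- x[rows, ] + matrix(shift, length(rows), 3,
                                          byrow = TRUE)
        }
      }
      x
    }
    P <- regularize_penalty(pos, kind, res_id, bonds, geo)
    lr <- 1e-3
    for (iter in seq_len(cfg$regularize_iter)) {
      G <- regularize_gradient(pos, kind, res_id, bonds, geo)
      if (max(abs(G)) < 1e-9) break
      accepted <- FALSE
      converged <- FALSE
      for (bt in 1:12) {
        cand <- project(pos - lr * G)
        Pc <- regularize_penalty(cand, kind, res_id, bonds, geo)
        if (Pc < P - 1e-12) {
          if (max(abs(cand - pos)) < 0.01) converged <- TRUE
          pos <- cand
          P <- Pc
          accepted <- TRUE
          lr <- lr * 1.5
          break
        }
        lr <- lr / 2
      }
      if (!accepted || converged) break
    }
    # write back; sidechain atoms follow their CA rigidly
    ca_delta <- matrix(0, nres, 3)
    for (k in seq_along(slots)) {
      i <- slots[[k]][1]
      row <- slots[[k]][2]
      if (kind[k] == "ca") {
        ca_delta[i, ] <- pos[k, ] - ch$residues[[i]]$atoms[row, ]
      }
    }
    for (k in seq_along(slots)) {
      i <- slots[[k]][1]
      row <- slots[[k]][2]
      ch$residues[[i]]$atoms[row, ] <- pos[k, ]
    }
    for (i in seq_len(nres)) {
      at <- ch$residues[[i]]$atoms
      side <- !rownames(at) %in% c(BACKBONE_ATOMS, "CB")
      if (any(side)) {
        at[side, ] <- at[side, , drop = FALSE] +
          matrix(ca_delta[i, ], sum(side), 3, byrow = TRUE)
        ch$residues[[i]]$atoms <- at
      }
    }
    s$chains[[ci]] <- ch
  }
  s
}

#' Build the final model from a raw modelling handle
#'
#' Runs deletion handling, database loop filling, the Monte Carlo fallback,
#' sidechain reconstruction and regularization; returns a complete model or
#' raises an error naming the unresolved gaps.
#'
#' @param mh a `modelling_handle` from [build_raw_model()].
#' @param cfg a [pipeline_config()].
#' @param lib a `rotamer_library` for sidechain reconstruction.
#' @param fdb,sdb fragment and structure databases (NULL skips database
#'   filling).
#' @param tables potentials from [train_potentials()] (NULL allowed when no
#'   gap needs filling).
#' @return a `structure3d`.
#' @export
build_from_raw_model <- function(mh, cfg = pipeline_config(), lib = NULL,
                                 fdb = NULL, sdb = NULL, tables = NULL) {
  mh <- handle_deletions(mh, cfg)
  if (length(mh$gaps) > 0 && !is.null(fdb) && !is.null(sdb)) {
    mh <- fill_loops_by_database(mh, fdb, sdb, tables, cfg)
  }
  if (length(mh$gaps) > 0) {
    if (is.null(tables)) {
      stop("unresolved gap(s) but no torsion tables for the Monte Carlo ",
           "fallback")
    }
    mh <- fill_loops_monte_carlo(mh, tables, cfg, seed = cfg$seed)
  }
  if (length(mh$gaps) > 0) {
    desc <- vapply(mh$gaps, function(g) {
      paste0("[", g$before, "-", g$after, " '", g$seq, "']")
    }, "")
    stop("unresolved gap(s): ", paste(desc, collapse = ", "))
  }
  s <- mh_to_structure(mh)
  if (!is.null(lib)) {
    s <- reconstruct_sidechains(s, lib, mode = cfg$rotamer_mode,
                                coverage = cfg$rotamer_coverage)
  }
  regularize(s, cfg)
}
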
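# Cyclic coordinate descent loop closure. The loop's first residue is pinned
# on the N-anchor; each sweep visits residues N -> C, phi then psi, applying
# the closed-form rotation that minimises the summed squared distance between
# the loop's last-residue (N, CA, C) and the C-anchor's (N, CA, C).

anchor_rmsd <- function(bb, c_anchor) {
  nres <- length(bb$seq)
  m <- rbind(bb$n[nres, ], bb$ca[nres, ], bb$c[nres, ])
  sqrt(mean(rowSums((m - c_anchor)^2)))
}

# optimal CCD rotation angle about the axis (p, u) for moving points `mov`
# targeting `fix` (paired rows); returns the angle maximising the alignment
ccd_angle <- function(mov, fix, p, u) {
  a <- 0
  b <- 0
  for (k in seq_len(nrow(mov))) {
    m <- mov[k, ]
    f <- fix[k, ]
    o <- p + u * sum((m - p) * u)
    rv <- m - o
    r <- vnorm(rv)
    if (r < 1e-10) next
    s_hat <- rv / r
    t_hat <- cross3(u, s_hat)
    fo <- f - o
    a <- a + r * sum(s_hat * fo)
    b <- b + r * sum(t_hat * fo)
  }
  if (a == 0 && b == 0) return(0)
  atan2(b, a)
}

#' Close a loop onto a C-anchor by cyclic coordinate descent
#'
#' The loop spans stem to stem: its first residue must already sit on the
#' N-anchor (it is never moved) and its last residue is driven onto
#' `c_anchor`. If the first residue's N/CA/C do not coincide with `n_anchor`
#' the loop is rigidly moved there first.
#'
#' @param loop a `backbone_list` with >= 3 residues.
#' @param n_anchor,c_anchor 3 x 3 matrices (rows N, CA, C) of the two stem
#'   residues.
#' @param max_iter maximum number of sweeps (default 200).
#' @param tol convergence threshold on the anchor RMSD (Angstrom,
#'   default 0.1).
#' @return list with `loop` (closed backbone), `converged` (logical),
#'   `anchor_rmsd` (Angstrom), `iterations` and `trace` (anchor RMSD after
#'   each sweep; monotone non-increasing).
#' @export
ccd_close <- function(loop, n_anchor, c_anchor, max_iter = 200, tol = 0.1) {
  nres <- length(loop$seq)
  if (nres < 3) stop("loop must have at least 3 residues")
  n_anchor <- as.matrix(n_anchor)
  c_anchor <- as.matrix(c_anchor)

  # pin the first residue onto the N-anchor if needed
  first <- rbind(loop$n[1, ], loop$ca[1, ], loop$c[1, ])
  if (max(abs(first - n_anchor)) > 1e-9) {
    fit <- kabsch(first, n_anchor)
    loop <- transform_backbone(loop, fit$rotation, fit$translation)
  }

  best <- anchor_rmsd(loop, c_anchor)
  trace <- best
  if (best <= tol) {
    return(list(loop = loop, converged = TRUE, anchor_rmsd = best,
                iterations = 0L, trace = trace))
  }

  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(nres)) {
      for (which in c("phi", "psi")) {
        cur <- if (which == "phi") loop$phi[i] else loop$psi[i]
        if (is.na(cur)) next
        if (which == "psi" && i == nres) next
        ax <- torsion_axis(loop, i, which)
        u <- unitv(ax$q - ax$p)
        # moving subset of the target atoms (last residue N, CA, C)
        if (i < nres) {
          mov <- rbind(loop$n[nres, ], loop$ca[nres, ], loop$c[nres, ])
          fix <- c_anchor
        } else {
          # phi of the last residue moves only its C atom
          mov <- rbind(loop$c[nres, ])
          fix <- c_anchor[3, , drop = FALSE]
        }
        theta <- ccd_angle(mov, fix, ax$p, u)
        if (abs(theta) > 1e-12) {
          loop <- set_torsion(loop, i, which, cur + theta)
        }
      }
    }
    best <- anchor_rmsd(loop, c_anchor)
    trace <- c(trace, best)
    if (best <= tol) {
      return(list(loop = loop, converged = TRUE, anchor_rmsd = best,
                  iterations = iter, trace = trace))
    }
  }
  list(loop = loop, converged = FALSE, anchor_rmsd = best, iterations = iter,
       trace = trace)
}
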
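# Rotamer-graph packing solvers: a rotamer graph holds per-position
# candidate self energies and sparse pairwise energy matrices. Solvers:
# exhaustive enumeration (test oracle), Goldstein dead-end elimination,
# edge decomposition, exact dynamic programming over a tree decomposition
# (min-fill bucket elimination), A* enumeration within an energy window and
# Metropolis Monte Carlo with geometric cooling.

#' Construct a rotamer graph
#'
#' @param self list of numeric vectors, one per position (candidate self
#'   energies).
#' @param edges list of `list(i, j, m)` with `m` a `|cand_i| x |cand_j|`
#'   pairwise energy matrix (i < j); absent edges are all-zero.
#' @param ids optional position identifiers.
#' @return object of class `rotamer_graph`.
#' @export
rotamer_graph <- function(self, edges = list(), ids = NULL) {
  np <- length(self)
  if (is.null(ids)) ids <- seq_len(np)
  for (e in edges) {
    if (e$i >= e$j) stop("edges must have i < j")
    if (!all(dim(e$m) == c(length(self[[e$i]]), length(self[[e$j]])))) {
      stop("edge (", e$i, ",", e$j, ") matrix shape mismatch")
    }
    if (any(!is.finite(e$m))) stop("non-finite pairwise energy")
  }
  structure(list(self = self, edges = edges, ids = ids, offset = 0),
            class = "rotamer_graph")
}

#' @export
print.rotamer_graph <- function(x, ...) {
  cat("<rotamer_graph> ", length(x$self), " positions, ", length(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

edge_matrix <- function(g, i, j) {
  for (e in g$edges) {
    if (e$i == i && e$j == j) return(e$m)
    if (e$i == j && e$j == i) return(t(e$m))
  }
  NULL
}

#' Total energy of a full assignment
#' @param g a `rotamer_graph`.
#' @param assignment integer vector of candidate indices, one per position.
#' @return energy including the graph's folded constant offset.
#' @export
graph_energy <- function(g, assignment) {
  E <- g$offset
  for (p in seq_along(g$self)) E <- E + g$self[[p]][assignment[p]]
  for (e in g$edges) E <- E + e$m[assignment[e$i], assignment[e$j]]
  E
}

#' Exhaustive minimum-energy assignment (test oracle)
#'
#' @param g a `rotamer_graph` with at most 1e7 combinations.
#' @return list with `assignment` (ties broken lexicographically) and
#'   `energy`.
#' @export
solve_brute_force <- function(g) {
  ks <- vapply(g$self, length, 0L)
  total <- prod(ks)
  if (total > 1e7) stop("search space too large for brute force: ", total)
  grid <- as.matrix(do.call(expand.grid, lapply(rev(ks), seq_len)))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # lexicographic rows
  E <- rep(g$offset, nrow(grid))
  for (p in seq_along(ks)) E <- E + g$self[[p]][grid[, p]]
  for (e in g$edges) E <- E + e$m[grid[, c(e$i, e$j), drop = FALSE]]
  best <- which.min(E)  # first minimum = lexicographically smallest
  list(assignment = as.integer(grid[best, ]), energy = E[best])
}

#' Goldstein dead-end elimination
#'
#' Iteratively removes candidate r at position i when some r' satisfies
#' `self(r) - self(r') + sum_j min_s [E(r,s) - E(r',s)] > 0`, which provably
#' cannot hurt the global optimum. Runs to a fixed point.
#'
#' @param g a `rotamer_graph`.
#' @return list with `graph` (pruned; matrices subset) and `kept` (list of
#'   retained candidate indices per position, mapping back to the input).
#' @export
dee_goldstein <- function(g) {
  np <- length(g$self)
  kept <- lapply(g$self, seq_along)
  self <- g$self
  edges <- g$edges
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(np)) {
      ki <- length(self[[i]])
      if (ki <= 1) next
      # pairwise contribution matrices vs each neighbour
      nb <- list()
      for (e in edges) {
        if (e$i == i) nb[[length(nb) + 1L]] <- e$m
        if (e$j == i) nb[[length(nb) + 1L]] <- t(e$m)
      }
      remove <- rep(FALSE, ki)
      for (r in seq_len(ki)) {
        for (rp in seq_len(ki)) {
          if (rp == r || remove[rp]) next
          margin <- self[[i]][r] - self[[i]][rp]
          for (m in nb) {
            margin <- margin + min(m[r, ] - m[rp, ])
          }
          if (margin > 0) {
            remove[r] <- TRUE
            break
          }
        }
      }
      if (any(remove)) {
        changed <- TRUE
        keep_idx <- which(!remove)
        kept[[i]] <- kept[[i]][keep_idx]
        self[[i]] <- self[[i]][keep_idx]
        for (k in seq_along(edges)) {
          if (edges[[k]]$i == i) {
            edges[[k]]$m <- edges[[k]]$m[keep_idx, , drop = FALSE]
          }
          if (edges[[k]]$j == i) {
            edges[[k]]$m <- edges[[k]]$m[, keep_idx, drop = FALSE]
          }
        }
      }
    }
  }
  g2 <- rotamer_graph(self, edges, g$ids)
  g2$offset <- g$offset
  list(graph = g2, kept = kept)
}

#' Edge decomposition
#'
#' Removes an edge when its matrix is additively separable up to `eps`
#' (tested by subtracting row minima then column minima); the separable
#' parts are folded into the self energies, so every full assignment's
#' energy changes by at most `eps` per removed edge.
#'
#' @param g a `rotamer_graph`.
#' @param eps non-negative tolerance (0 removes only exactly separable
#'   edges).
#' @return list with `graph` and `removed` (count).
#' @export
edge_decompose <- function(g, eps = 0) {
  stopifnot(eps >= 0)
  self <- g$self
  keep <- list()
  removed <- 0L
  for (e in g$edges) {
    u <- apply(e$m, 1, min)
    R <- e$m - u
    v <- apply(R, 2, min)
    resid <- sweep(R, 2, v)
    if (max(resid) <= eps + 1e-12) {
      self[[e$i]] <- self[[e$i]] + u
      self[[e$j]] <- self[[e$j]] + v
      removed <- removed + 1L
    } else {
      keep[[length(keep) + 1L]] <- e
    }
  }
  g2 <- rotamer_graph(self, keep, g$ids)
  g2$offset <- g$offset
  list(graph = g2, removed = removed)
}

# ---- tree-decomposition dynamic programming -------------------------------

min_fill_order <- function(adj) {
  np <- nrow(adj)
  alive <- rep(TRUE, np)
  order <- integer(0)
  width <- 0L
  A <- adj
  for (step in seq_len(np)) {
    cand <- which(alive)
    fill <- vapply(cand, function(v) {
      nbs <- which(alive & A[v, ])
      nbs <- setdiff(nbs, v)
      if (length(nbs) < 2) return(0L)
      cnt <- 0L
      for (a in seq_along(nbs)) {
        for (b in seq_len(a - 1L)) {
          if (!A[nbs[a], nbs[b]]) cnt <- cnt + 1L
        }
      }
      cnt
    }, 0L)
    v <- cand[which.min(fill)]
    nbs <- setdiff(which(alive & A[v, ]), v)
    width <- max(width, length(nbs))
    if (length(nbs) > 1) {
      for (a in seq_along(nbs)) {
        for (b in seq_len(a - 1L)) {
          A[nbs[a], nbs[b]] <- TRUE
          A[nbs[b], nbs[a]] <- TRUE
        }
      }
    }
    alive[v] <- FALSE
    order <- c(order, v)
  }
  list(order = order, width = width)
}

expand_factor <- function(tab, vars, allvars, ks) {
  miss <- setdiff(allvars, vars)
  dims <- c(ks[vars], ks[miss])
  full <- array(rep(as.vector(tab), times = prod(ks[miss])), dim = dims)
  cur <- c(vars, miss)
  aperm(full, match(allvars, cur))
}

#' Exact optimum by dynamic programming over a tree decomposition
#'
#' Bucket (variable) elimination along a min-fill order; exact on every
#' instance whose induced width is within `width_cap`.
#'
#' @param g a `rotamer_graph`.
#' @param width_cap maximum allowed induced width (default 12).
#' @return list with `assignment` and `energy` (equals the brute-force
#'   optimum).
#' @export
solve_treepack <- function(g, width_cap = 12) {
  np <- length(g$self)
  ks <- vapply(g$self, length, 0L)
  adj <- matrix(FALSE, np, np)
  for (e in g$edges) {
    adj[e$i, e$j] <- TRUE
    adj[e$j, e$i] <- TRUE
  }
  mf <- min_fill_order(adj)
  if (mf$width > width_cap) {
    stop("tree width ", mf$width, " exceeds cap ", width_cap,
         "; use solve_astar or solve_monte_carlo")
  }
  factors <- list()
  for (p in seq_len(np)) {
    factors[[length(factors) + 1L]] <- list(vars = p,
                                            tab = array(g$self[[p]], ks[p]))
  }
  for (e in g$edges) {
    factors[[length(factors) + 1L]] <-
      list(vars = c(e$i, e$j), tab = array(e$m, c(ks[e$i], ks[e$j])))
  }
  records <- list()
  const <- g$offset
  for (v in mf$order) {
    has_v <- vapply(factors, function(f) v %in% f$vars, TRUE)
    fs <- factors[has_v]
    factors <- factors[!has_v]
    allvars <- sort(unique(unlist(lapply(fs, `[[`, "vars"))))
    psi <- array(0, dim = ks[allvars])
    for (f in fs) psi <- psi + expand_factor(f$tab, f$vars, allvars, ks)
    vd <- match(v, allvars)
    others <- allvars[-vd]
    if (length(others) == 0) {
      arg <- which.min(psi)
      records[[length(records) + 1L]] <- list(var = v, others = others,
                                              argmin = arg)
      const <- const + psi[arg]
    } else {
      perm <- aperm(psi, c(vd, seq_along(allvars)[-vd]))
      m <- matrix(perm, nrow = ks[v])
      idx <- max.col(-t(m), ties.method = "first")
      tau <- m[cbind(idx, seq_along(idx))]
      records[[length(records) + 1L]] <- list(
        var = v, others = others,
        argmin = array(idx, dim = ks[others]))
      factors[[length(factors) + 1L]] <- list(
        vars = others, tab = array(tau, dim = ks[others]))
    }
  }
  assignment <- rep(NA_integer_, np)
  for (r in rev(records)) {
    if (length(r$others) == 0) {
      assignment[r$var] <- r$argmin
    } else {
      sub <- as.matrix(t(assignment[r$others]))
      assignment[r$var] <- r$argmin[sub]
    }
  }
  list(assignment = assignment, energy = graph_energy(g, assignment))
}

# ---- A* enumeration -------------------------------------------------------

#' Enumerate all assignments within an energy window by A*
#'
#' Best-first search over positions ordered by increasing candidate count.
#' The admissible heuristic sums, per unassigned position, the minimum of
#' self energy plus best-case pairwise energy to the assigned part, plus the
#' (non-positive part of the) best-case pairwise energies among unassigned
#' pairs.
#'
#' @param g a `rotamer_graph`.
#' @param window energy window above the optimum (0 = optimum only;
#'   `Inf` = everything).
#' @param max_solutions cap on the returned list; when hit, the result
#'   carries `truncated = TRUE`.
#' @return list with `solutions` (list of `list(assignment, energy)` sorted
#'   by increasing energy) and `truncated`.
#' @export
solve_astar <- function(g, window = 0, max_solutions = 10000L) {
  np <- length(g$self)
  ks <- vapply(g$self, length, 0L)
  ord <- order(ks, seq_len(np))
  pair_min <- matrix(0, np, np)
  for (e in g$edges) {
    pair_min[e$i, e$j] <- min(e$m)
    pair_min[e$j, e$i] <- pair_min[e$i, e$j]
  }
  heur <- function(assigned) {
    un <- ord[(length(assigned) + 1L):np]
    if (length(assigned) == np) return(0)
    h <- 0
    for (p in un) {
      best <- Inf
      for (r in seq_len(ks[p])) {
        v <- g$self[[p]][r]
        for (qi in seq_along(assigned)) {
          q <- ord[qi]
          m <- edge_matrix(g, q, p)
          if (!is.null(m)) v <- v + m[assigned[qi], r]
        }
        best <- min(best, v)
      }
      h <- h + best
    }
    # admissible bound for interactions among unassigned pairs
    for (a in seq_along(un)) {
      for (b in seq_len(a - 1L)) {
        h <- h + min(0, pair_min[un[a], un[b]])
      }
    }
    h
  }
  gcost <- function(assigned) {
    E <- g$offset
    for (qi in seq_along(assigned)) {
      p <- ord[qi]
      E <- E + g$self[[p]][assigned[qi]]
      for (ri in seq_len(qi - 1L)) {
        m <- edge_matrix(g, ord[ri], p)
        if (!is.null(m)) E <- E + m[assigned[ri], assigned[qi]]
      }
    }
    E
  }
  queue <- list(list(assigned = integer(0), f = heur(integer(0))))
  solutions <- list()
  opt <- NA_real_
  truncated <- FALSE
  while (length(queue) > 0) {
    fs <- vapply(queue, `[[`, 0, "f")
    k <- which.min(fs)
    node <- queue[[k]]
    queue[[k]] <- NULL
    if (!is.na(opt) && node$f > opt + window + 1e-12) break
    if (length(node$assigned) == np) {
      if (is.na(opt)) opt <- node$f
      if (node$f <= opt + window + 1e-12) {
        assignment <- integer(np)
        assignment[ord] <- node$assigned
        solutions[[length(solutions) + 1L]] <-
          list(assignment = assignment, energy = node$f)
        if (length(solutions) >= max_solutions) {
          truncated <- TRUE
          break
        }
      }
      next
    }
    p <- ord[length(node$assigned) + 1L]
    for (r in seq_len(ks[p])) {
      assigned <- c(node$assigned, r)
      f <- gcost(assigned) + heur(assigned)
      queue[[length(queue) + 1L]] <- list(assigned = assigned, f = f)
    }
  }
  ord_sol <- order(vapply(solutions, `[[`, 0, "energy"))
  list(solutions = solutions[ord_sol], truncated = truncated)
}

#' Metropolis Monte Carlo packing with geometric cooling
#'
#' Single-position rotamer flips, visiting positions cyclically and
#' proposing a uniformly drawn alternative rotamer; the temperature is
#' multiplied by `cool` after every sweep (`n_positions` steps). Returns the
#' best state seen; reproducible for a fixed seed.
#'
#' @param g a `rotamer_graph`.
#' @param steps total number of flip attempts (>= 1).
#' @param T0 initial temperature (energy units).
#' @param cool geometric cooling factor per sweep.
#' @param seed RNG seed.
#' @return list with `assignment` and `energy`.
#' @export
solve_monte_carlo <- function(g, steps = 5000, T0 = 10, cool = 0.9,
                              seed = 1) {
  stopifnot(steps >= 1)
  np <- length(g$self)
  ks <- vapply(g$self, length, 0L)
  set.seed(seed)
  cur <- vapply(seq_len(np), function(p) sample.int(ks[p], 1), 0L)
  curE <- graph_energy(g, cur)
  best <- cur
  bestE <- curE
  Temp <- T0
  for (s in seq_len(steps)) {
    p <- ((s - 1L) %% np) + 1L
    if (ks[p] == 1) next
    r_new <- sample.int(ks[p] - 1L, 1)
    if (r_new >= cur[p]) r_new <- r_new + 1L  # exclude the current rotamer
    dE <- g$self[[p]][r_new] - g$self[[p]][cur[p]]
    for (e in g$edges) {
      if (e$i == p) dE <- dE + e$m[r_new, cur[e$j]] - e$m[cur[p], cur[e$j]]
      if (e$j == p) dE <- dE + e$m[cur[e$i], r_new] - e$m[cur[e$i], cur[p]]
    }
    if (dE <= 0 || stats::runif(1) < exp(-dE / max(Temp, 1e-9))) {
      cur[p] <- r_new
      curE <- curE + dE
      if (curE < bestE - 1e-12) {
        best <- cur
        bestE <- curE
      }
    }
    if (s %% np == 0) Temp <- Temp * cool
  }
  list(assignment = best, energy = graph_energy(g, best))
}

#' Sub-rotamer optimization of a flexible-rotamer solution
#'
#' Expands each selected flexible rotamer into its rigid sub-rotamers and
#' re-solves the reduced rigid graph exactly (tree decomposition, A*
#' fallback). The central assignment is part of the search space, so the
#' rigid energy never increases relative to it.
#'
#' @param flex_selected list of selected `flexible_rotamer`s (one per
#'   position).
#' @param frame optional fixed-frame atom table (see [frame_energy()]).
#' @param radii hard-sphere radius table.
#' @return list with `rotamers` (chosen rigid sub-rotamers), `sub_indices`,
#'   `energy` and `central_energy` (both rigid evaluations).
#' @export
subrotamer_optimize <- function(flex_selected, frame = NULL,
                                radii = CLASH_RADII) {
  np <- length(flex_selected)
  self <- vector("list", np)
  for (p in seq_len(np)) {
    fr <- flex_selected[[p]]
    stopifnot(inherits(fr, "flexible_rotamer"))
    self[[p]] <- vapply(fr$subs, function(s) {
      e <- s$self_energy
      if (!is.null(frame)) e <- e + frame_energy(s, frame, radii = radii)
      e
    }, 0)
  }
  edges <- list()
  if (np >= 2) {
    for (i in seq_len(np - 1)) {
      for (j in (i + 1):np) {
        si <- flex_selected[[i]]$subs
        sj <- flex_selected[[j]]$subs
        m <- matrix(0, length(si), length(sj))
        for (a in seq_along(si)) {
          ea <- rotamer_elements(si[[a]])
          for (b in seq_along(sj)) {
            m[a, b] <- rigid_atom_energy(si[[a]]$atoms, ea, sj[[b]]$atoms,
                                         rotamer_elements(sj[[b]]), radii)
          }
        }
        if (any(m != 0)) edges[[length(edges) + 1L]] <- list(i = i, j = j,
                                                             m = m)
      }
    }
  }
  g <- rotamer_graph(self, edges)
  sol <- tryCatch(solve_treepack(g),
                  error = function(e) solve_astar(g, 0)$solutions[[1]])
  central <- rep(1L, np)
  list(rotamers = lapply(seq_len(np), function(p) {
         flex_selected[[p]]$subs[[sol$assignment[p]]]
       }),
       sub_indices = sol$assignment,
       energy = sol$energy,
       central_energy = graph_energy(g, central))
}
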
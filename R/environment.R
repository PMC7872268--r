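# ScoringEnvironment: backbone of the full current model with per-residue
# set/unset flags and a cell-list spatial hash over the heavy backbone atoms
# plus CB, so scorers can retrieve neighbours in O(1) per query.

ENV_ATOMS <- c("n", "ca", "c", "o", "cb")

#' Create a scoring environment
#'
#' @param seq one-letter sequence of the full model (single chain).
#' @param cell_size spatial-hash cell size in Angstrom; use the maximum
#'   scorer cutoff (default 15).
#' @return object of class `scoring_env` with all residues unset.
#' @export
env_new <- function(seq, cell_size = 15) {
  seq1 <- if (length(seq) == 1) strsplit(seq, "")[[1]] else seq
  nres <- length(seq1)
  coords <- lapply(ENV_ATOMS, function(a) matrix(NA_real_, nres, 3))
  names(coords) <- ENV_ATOMS
  structure(list(seq = seq1, coords = coords,
                 set = rep(FALSE, nres), cell_size = cell_size,
                 hash = NULL),
            class = "scoring_env")
}

#' Set environment residues from a backbone
#'
#' @param env a `scoring_env`.
#' @param bb a `backbone_list` covering `at`.
#' @param at integer residue indices in the model (1-based), same length as
#'   `bb`.
#' @return updated environment.
#' @export
env_set <- function(env, bb, at) {
  if (any(at < 1 | at > length(env$seq))) stop("residue range out of bounds")
  if (length(at) != length(bb$seq)) stop("backbone/range length mismatch")
  env$coords$n[at, ] <- bb$n
  env$coords$ca[at, ] <- bb$ca
  env$coords$c[at, ] <- bb$c
  env$coords$o[at, ] <- bb$o
  env$coords$cb[at, ] <- bb$cb
  env$set[at] <- TRUE
  env$hash <- NULL
  env
}

#' Clear environment residues
#' @param env a `scoring_env`.
#' @param at integer residue indices to unset.
#' @return updated environment.
#' @export
env_clear <- function(env, at) {
  if (any(at < 1 | at > length(env$seq))) stop("residue range out of bounds")
  for (a in ENV_ATOMS) env$coords[[a]][at, ] <- NA_real_
  env$set[at] <- FALSE
  env$hash <- NULL
  env
}

# flat atom table over set residues: matrix pos (k x 3), residue index,
# atom kind; plus the cell hash (environment mapping cell key -> atom rows)
env_atom_table <- function(env) {
  if (!is.null(env$hash)) return(env$hash)
  set_idx <- which(env$set)
  pos <- NULL
  res <- integer(0)
  kind <- character(0)
  for (a in ENV_ATOMS) {
    m <- env$coords[[a]][set_idx, , drop = FALSE]
    ok <- !is.na(m[, 1])
    pos <- rbind(pos, m[ok, , drop = FALSE])
    res <- c(res, set_idx[ok])
    kind <- c(kind, rep(a, sum(ok)))
  }
  cells <- new.env(parent = emptyenv(), hash = TRUE)
  if (length(res) > 0) {
    key <- paste(floor(pos[, 1] / env$cell_size),
                 floor(pos[, 2] / env$cell_size),
                 floor(pos[, 3] / env$cell_size))
    sp <- split(seq_along(res), key)
    for (k in names(sp)) assign(k, sp[[k]], envir = cells)
  }
  list(pos = pos, res = res, kind = kind, cells = cells)
}

#' Neighbour atoms within a radius
#'
#' Cell-list lookup over the set part of the environment.
#'
#' @param env a `scoring_env`.
#' @param point length-3 query position.
#' @param radius search radius in Angstrom (must be <= the cell size).
#' @return data.frame with `res` (residue index), `kind` (atom kind) and
#'   `dist` for every set atom within `radius`.
#' @export
env_neighbors <- function(env, point, radius) {
  if (radius > env$cell_size) stop("radius exceeds the hash cell size")
  tab <- env_atom_table(env)
  if (length(tab$res) == 0) {
    return(data.frame(res = integer(0), kind = character(0),
                      dist = numeric(0)))
  }
  base <- floor(point / env$cell_size)
  rows <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(base[1] + dx, base[2] + dy, base[3] + dz)
    if (exists(k, envir = tab$cells, inherits = FALSE)) {
      rows <- c(rows, get(k, envir = tab$cells))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(res = integer(0), kind = character(0),
                      dist = numeric(0)))
  }
  d <- sqrt(rowSums(sweep(tab$pos[rows, , drop = FALSE], 2, point)^2))
  keep <- d <= radius
  data.frame(res = tab$res[rows[keep]], kind = tab$kind[rows[keep]],
             dist = d[keep])
}

# CB position with CA fallback (glycine) for residue i; NA if unset
env_cb <- function(env, i) {
  if (!env$set[i]) return(rep(NA_real_, 3))
  cb <- env$coords$cb[i, ]
  if (is.na(cb[1])) env$coords$ca[i, ] else cb
}

# measured phi/psi of residue i from the environment (NA at unset neighbours)
env_phi_psi <- function(env, i) {
  nres <- length(env$seq)
  phi <- NA_real_
  psi <- NA_real_
  if (i > 1 && env$set[i - 1] && env$set[i]) {
    phi <- dihedral(env$coords$c[i - 1, ], env$coords$n[i, ],
                    env$coords$ca[i, ], env$coords$c[i, ])
  }
  if (i < nres && env$set[i] && env$set[i + 1]) {
    psi <- dihedral(env$coords$n[i, ], env$coords$ca[i, ],
                    env$coords$c[i, ], env$coords$n[i + 1, ])
  }
  c(phi, psi)
}
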
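# FragDB: fragment index keyed by discretized stem geometry. The relative
# orientation of the two stem residues flanking a fragment is reduced to six
# descriptors (l, d, alpha, beta, gamma, delta); discretizing the continuous
# five yields a hash key giving O(1) access to all fragments with similar
# stem geometry.

stem_frame <- function(stem) {
  # stem: 3 x 3 matrix with rows N, CA, C
  x <- unitv(stem[3, ] - stem[2, ])
  zc <- cross3(x, stem[1, ] - stem[2, ])
  if (vnorm(zc) < 1e-8) stop("collinear stem atoms")
  z <- unitv(zc)
  y <- cross3(z, x)
  list(x = x, y = y, z = z)
}

#' Six-descriptor geometry of a stem pair
#'
#' `d` is the distance from the N-stem C atom to the C-stem N atom. The
#' angles (alpha, beta) are the polar/azimuth direction of that inter-anchor
#' vector in the N-stem frame (x = CA->C, z = x cross CA->N, y = z cross x);
#' (gamma, delta) describe the reverse vector in the C-stem frame. `l` is the
#' number of residues between the stems and is passed through.
#'
#' @param n_stem,c_stem 3 x 3 matrices (rows N, CA, C) of the two stem
#'   residues.
#' @param l number of residues between the stems.
#' @return list of class `stem_geometry` with fields `l`, `d`, `alpha`,
#'   `beta`, `gamma`, `delta` (angles in radians; polar in `[0, pi]`,
#'   azimuth in `(-pi, pi]`).
#' @export
stem_geometry <- function(n_stem, c_stem, l) {
  n_stem <- as.matrix(n_stem)
  c_stem <- as.matrix(c_stem)
  v <- c_stem[1, ] - n_stem[3, ]   # N-stem C -> C-stem N
  d <- vnorm(v)
  if (d < 1e-8) stop("degenerate stems: anchors coincide")
  vn <- v / d
  fn <- stem_frame(n_stem)
  fc <- stem_frame(c_stem)
  pol <- function(f, u) {
    list(polar = acos(max(-1, min(1, sum(u * f$z)))),
         azimuth = atan2(sum(u * f$y), sum(u * f$x)))
  }
  pn <- pol(fn, vn)
  pc <- pol(fc, -vn)
  structure(list(l = as.integer(l), d = d, alpha = pn$polar,
                 beta = pn$azimuth, gamma = pc$polar, delta = pc$azimuth),
            class = "stem_geometry")
}

stem_key_bins <- function(g, dist_bin, angle_bin) {
  ab <- angle_bin * pi / 180
  c(floor(g$d / dist_bin), floor(g$alpha / ab), floor(g$beta / ab),
    floor(g$gamma / ab), floor(g$delta / ab))
}

stem_key <- function(l, bins) {
  paste(c(l, bins), collapse = ",")
}

#' Create an empty FragDB
#'
#' @param dist_bin distance bin width in Angstrom (default 1.0).
#' @param angle_bin angle bin width in degrees (default 20).
#' @return object of class `frag_db`.
#' @export
fragdb_new <- function(dist_bin = 1.0, angle_bin = 20) {
  structure(list(dist_bin = dist_bin, angle_bin = angle_bin,
                 max_pairwise_rmsd = NA_real_,
                 buckets = list(), n_fragments = 0L),
            class = "frag_db")
}

#' @export
print.frag_db <- function(x, ...) {
  cat("<frag_db> ", x$n_fragments, " fragments in ", length(x$buckets),
      " buckets (dist_bin ", x$dist_bin, " A, angle_bin ", x$angle_bin,
      " deg)\n", sep = "")
  invisible(x)
}

# fragment-with-stems backbone (length + 2 residues) for a candidate
fragment_with_stems <- function(db, chain_index, offset, length) {
  db_get_fragment(db, fragment_address(chain_index, offset - 1L,
                                       length + 2L))$bb
}

# CA-RMSD of two fragment interiors after superposing on the 6 stem atoms
stem_superposed_rmsd <- function(bb_a, bb_b) {
  L <- length(bb_a$seq)
  stem_idx <- c(1L, L)
  A <- rbind(bb_a$n[stem_idx, ], bb_a$ca[stem_idx, ], bb_a$c[stem_idx, ])
  B <- rbind(bb_b$n[stem_idx, ], bb_b$ca[stem_idx, ], bb_b$c[stem_idx, ])
  fit <- kabsch(A, B)
  inner <- 2:(L - 1)
  moved <- bb_a$ca[inner, , drop = FALSE] %*% t(fit$rotation) +
    matrix(fit$translation, length(inner), 3, byrow = TRUE)
  sqrt(mean(rowSums((moved - bb_b$ca[inner, , drop = FALSE])^2)))
}

# stem geometry of a stored fragment candidate (stems just outside)
db_stem_geometry <- function(db, chain_index, offset, length) {
  ch <- db$chains[[chain_index]]
  i_n <- offset            # 1-based index of N-stem residue (= offset 0-based - 1)
  i_c <- offset + length + 1L
  n_stem <- rbind(ch$n[i_n, ], ch$ca[i_n, ], ch$c[i_n, ])
  c_stem <- rbind(ch$n[i_c, ], ch$ca[i_c, ], ch$c[i_c, ])
  stem_geometry(n_stem, c_stem, length)
}

#' Index all fragments of one length into a FragDB
#'
#' Every contiguous fragment of the given length whose flanking stem
#' residues exist is considered in deterministic order (chain order, then
#' offset). A fragment is stored unless an already-stored fragment in the
#' same bucket is within `rmsd_thresh` CA-RMSD after superposition on the
#' stem atoms.
#'
#' @param fdb a `frag_db`.
#' @param length fragment length (residues between the stems).
#' @param rmsd_thresh redundancy threshold in Angstrom (0 disables).
#' @param db the `structure_db` the addresses refer to.
#' @return list with `fdb` (updated) and `added` (count of stored fragments).
#' @export
fragdb_add_fragments <- function(fdb, length, rmsd_thresh, db) {
  stopifnot(inherits(fdb, "frag_db"), inherits(db, "structure_db"))
  if (length < 1) stop("fragment length must be >= 1")
  added <- 0L
  for (ci in seq_along(db$chains)) {
    L <- db_chain_length(db, ci)
    if (L < length + 2L) next
    for (off in 1:(L - length - 1L)) {  # 0-based fragment offsets
      g <- db_stem_geometry(db, ci, off, length)
      key <- stem_key(g$l, stem_key_bins(g, fdb$dist_bin, fdb$angle_bin))
      bucket <- fdb$buckets[[key]]
      cand_bb <- NULL
      redundant <- FALSE
      if (!is.null(bucket) && rmsd_thresh > 0) {
        cand_bb <- fragment_with_stems(db, ci, off, length)
        for (addr in bucket) {
          if (addr$length != length) next
          stored_bb <- fragment_with_stems(db, addr$chain_index, addr$offset,
                                           addr$length)
          if (stem_superposed_rmsd(cand_bb, stored_bb) < rmsd_thresh) {
            redundant <- TRUE
            break
          }
        }
      }
      if (!redundant) {
        addr <- fragment_address(ci, off, length)
        if (is.null(bucket)) fdb$buckets[[key]] <- list(addr)
        else fdb$buckets[[key]] <- c(bucket, list(addr))
        fdb$n_fragments <- fdb$n_fragments + 1L
        added <- added + 1L
      }
    }
  }
  fdb$max_pairwise_rmsd <- rmsd_thresh
  list(fdb = fdb, added = added)
}

#' Query a FragDB by stem geometry
#'
#' Returns the union of all buckets whose discretized keys lie within
#' `extra_bins` of the query key in every dimension (same `l`), ordered by
#' Chebyshev bin distance (exact bucket first), ties by insertion order.
#'
#' @param fdb a `frag_db`.
#' @param g a [stem_geometry()].
#' @param extra_bins half-width of the search window in bins (default 0).
#' @return list of [fragment_address()] (possibly empty).
#' @export
fragdb_query <- function(fdb, g, extra_bins = 0L) {
  base <- stem_key_bins(g, fdb$dist_bin, fdb$angle_bin)
  out <- list()
  if (extra_bins == 0) {
    b <- fdb$buckets[[stem_key(g$l, base)]]
    return(if (is.null(b)) list() else b)
  }
  offs <- -extra_bins:extra_bins
  grid <- as.matrix(expand.grid(offs, offs, offs, offs, offs))
  cheb <- apply(abs(grid), 1, max)
  for (dist in 0:extra_bins) {
    rows <- which(cheb == dist)
    # deterministic order within one Chebyshev shell
    rows <- rows[order(grid[rows, 1], grid[rows, 2], grid[rows, 3],
                       grid[rows, 4], grid[rows, 5])]
    for (r in rows) {
      key <- stem_key(g$l, base + grid[r, ])
      b <- fdb$buckets[[key]]
      if (!is.null(b)) out <- c(out, b)
    }
  }
  out
}

#' Save / load a FragDB in its binary container format
#' @param fdb a `frag_db`.
#' @param path file path.
#' @return `save_frag_db`: invisibly `path`; `load_frag_db`: the `frag_db`.
#' @export
save_frag_db <- function(fdb, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HMFD"), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(fdb$dist_bin, fdb$angle_bin, fdb$max_pairwise_rmsd), con,
           size = 8, endian = "little")
  writeBin(length(fdb$buckets), con, size = 4, endian = "little")
  for (key in names(fdb$buckets)) {
    write_bin_string(con, key)
    bucket <- fdb$buckets[[key]]
    writeBin(length(bucket), con, size = 4, endian = "little")
    for (addr in bucket) {
      writeBin(c(addr$chain_index, addr$offset, addr$length), con,
               size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname save_frag_db
#' @export
load_frag_db <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "HMFD") stop("not a FragDB file: bad magic '", magic, "'")
  ver <- readBin(con, "integer", size = 4, endian = "little")
  if (ver != 1L) stop("unsupported FragDB version ", ver)
  pars <- readBin(con, "double", n = 3, size = 8, endian = "little")
  fdb <- fragdb_new(pars[1], pars[2])
  fdb$max_pairwise_rmsd <- pars[3]
  nb <- readBin(con, "integer", size = 4, endian = "little")
  nfrag <- 0L
  for (k in seq_len(nb)) {
    key <- read_bin_string(con)
    nad <- readBin(con, "integer", size = 4, endian = "little")
    bucket <- vector("list", nad)
    for (a in seq_len(nad)) {
      v <- readBin(con, "integer", n = 3, size = 4, endian = "little")
      bucket[[a]] <- fragment_address(v[1], v[2], v[3])
    }
    fdb$buckets[[key]] <- bucket
    nfrag <- nfrag + nad
  }
  fdb$n_fragments <- nfrag
  fdb
}
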
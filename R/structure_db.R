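# StructureDB: a linear store of chain backbone data (sequence, N/CA/C/O
# coordinates, phi/psi, secondary structure). Any fragment is addressable by
# (chain_index, offset, length) with a 0-based offset.

#' Create an empty StructureDB
#' @return object of class `structure_db`.
#' @export
db_new <- function() {
  structure(list(chains = list()), class = "structure_db")
}

#' @export
print.structure_db <- function(x, ...) {
  nres <- sum(vapply(x$chains, function(ch) nchar(ch$sequence), 0))
  cat("<structure_db> ", length(x$chains), " chain(s), ", nres,
      " residues\n", sep = "")
  invisible(x)
}

#' Add a chain to a StructureDB
#'
#' The backbone's sequence must be a contiguous subsequence of `seqres`
#' (this minimal dialect allows truncation at the termini only). Secondary
#' structure is assigned on insertion.
#'
#' @param db a `structure_db`.
#' @param id entry identifier (e.g. a PDB id).
#' @param chain_name chain name within the entry.
#' @param bb a `backbone_list`.
#' @param seqres full construct sequence; defaults to the backbone sequence.
#' @return list with `db` (updated) and `chain_index` (1-based stable index).
#' @export
db_add_chain <- function(db, id, chain_name, bb, seqres = NULL) {
  stopifnot(inherits(db, "structure_db"), inherits(bb, "backbone_list"))
  bbseq <- paste(bb$seq, collapse = "")
  if (is.null(seqres)) seqres <- bbseq
  if (!grepl(bbseq, seqres, fixed = TRUE)) {
    stop("backbone sequence is not a contiguous subsequence of seqres")
  }
  entry <- list(id = id, chain_name = chain_name, sequence = bbseq,
                n = bb$n, ca = bb$ca, c = bb$c, o = bb$o,
                phi = bb$phi, psi = bb$psi, ss = assign_ss(bb))
  db$chains[[length(db$chains) + 1L]] <- entry
  list(db = db, chain_index = length(db$chains))
}

#' Number of residues of a StructureDB chain
#' @param db a `structure_db`.
#' @param chain_index 1-based chain index.
#' @return integer length.
#' @export
db_chain_length <- function(db, chain_index) {
  nchar(db$chains[[chain_index]]$sequence)
}

check_address <- function(db, addr) {
  if (addr$chain_index < 1 || addr$chain_index > length(db$chains)) {
    stop("chain index ", addr$chain_index, " out of range")
  }
  L <- db_chain_length(db, addr$chain_index)
  if (addr$length < 1 || addr$offset < 0 || addr$offset + addr$length > L) {
    stop("fragment address (offset ", addr$offset, ", length ", addr$length,
         ") out of range for chain of length ", L)
  }
}

#' Fragment address constructor
#' @param chain_index 1-based chain index in a StructureDB.
#' @param offset 0-based residue offset from the chain start.
#' @param length fragment length in residues.
#' @return list of class `fragment_address`.
#' @export
fragment_address <- function(chain_index, offset, length) {
  structure(list(chain_index = as.integer(chain_index),
                 offset = as.integer(offset), length = as.integer(length)),
            class = "fragment_address")
}

#' Fetch a fragment from a StructureDB
#'
#' @param db a `structure_db`.
#' @param addr a [fragment_address()].
#' @return list with `bb` (a `backbone_list`), `sequence` and `ss` strings.
#' @export
db_get_fragment <- function(db, addr) {
  check_address(db, addr)
  ch <- db$chains[[addr$chain_index]]
  idx <- (addr$offset + 1):(addr$offset + addr$length)
  seq1 <- strsplit(ch$sequence, "")[[1]][idx]
  bb <- new_backbone(seq1, ch$n[idx, , drop = FALSE],
                     ch$ca[idx, , drop = FALSE], ch$c[idx, , drop = FALSE],
                     ch$o[idx, , drop = FALSE])
  list(bb = bb,
       sequence = paste(seq1, collapse = ""),
       ss = paste(strsplit(ch$ss, "")[[1]][idx], collapse = ""))
}

# ---- binary serialization -------------------------------------------------

write_bin_string <- function(con, s) {
  raw <- charToRaw(s)
  writeBin(length(raw), con, size = 4, endian = "little")
  writeBin(raw, con)
}

read_bin_string <- function(con) {
  n <- readBin(con, "integer", size = 4, endian = "little")
  rawToChar(readBin(con, "raw", n = n))
}

write_bin_doubles <- function(con, x) {
  x <- as.numeric(x)
  x[is.na(x)] <- NaN
  writeBin(length(x), con, size = 4, endian = "little")
  writeBin(x, con, size = 8, endian = "little")
}

read_bin_doubles <- function(con) {
  n <- readBin(con, "integer", size = 4, endian = "little")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  x[is.nan(x)] <- NA_real_
  x
}

#' Save / load a StructureDB in its binary container format
#'
#' Versioned header followed by little-endian packed arrays; a save/load
#' round trip is byte-stable.
#'
#' @param db a `structure_db`.
#' @param path file path.
#' @return `save_structure_db`: invisibly `path`; `load_structure_db`: the
#'   `structure_db`.
#' @export
save_structure_db <- function(db, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HMDB"), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(length(db$chains), con, size = 4, endian = "little")
  for (ch in db$chains) {
    write_bin_string(con, ch$id)
    write_bin_string(con, ch$chain_name)
    write_bin_string(con, ch$sequence)
    write_bin_string(con, ch$ss)
    for (f in c("n", "ca", "c", "o")) write_bin_doubles(con, ch[[f]])
    write_bin_doubles(con, ch$phi)
    write_bin_doubles(con, ch$psi)
  }
  invisible(path)
}

#' @rdname save_structure_db
#' @export
load_structure_db <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "HMDB") stop("not a StructureDB file: bad magic '", magic, "'")
  ver <- readBin(con, "integer", size = 4, endian = "little")
  if (ver != 1L) stop("unsupported StructureDB version ", ver)
  nch <- readBin(con, "integer", size = 4, endian = "little")
  db <- db_new()
  for (k in seq_len(nch)) {
    id <- read_bin_string(con)
    chain_name <- read_bin_string(con)
    sequence <- read_bin_string(con)
    ss <- read_bin_string(con)
    L <- nchar(sequence)
    coords <- lapply(1:4, function(i) matrix(read_bin_doubles(con), L, 3))
    phi <- read_bin_doubles(con)
    psi <- read_bin_doubles(con)
    db$chains[[k]] <- list(id = id, chain_name = chain_name,
                           sequence = sequence, n = coords[[1]],
                           ca = coords[[2]], c = coords[[3]], o = coords[[4]],
                           phi = phi, psi = psi, ss = ss)
  }
  db
}
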
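# Structure and alignment I/O: PDB (read/write), minimal mmCIF (read),
# FASTA alignments, and binding of alignment rows to template chains.
#
# Internal residue indexing is 0-based contiguous per chain; author numbering
# and insertion codes are preserved only for I/O.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_residue <- function(number, icode, name, atoms, occupancy = NULL,
                        bfactor = NULL) {
  list(number = number, icode = icode, name = name,
       one_letter = aa_three_to_one(name), atoms = atoms,
       occupancy = occupancy, bfactor = bfactor)
}

#' Construct a Structure object
#'
#' A Structure is a list of chains; each chain holds an ordered list of
#' residues with a named-row coordinate matrix per residue. Most users obtain
#' one from [read_structure()] or from the fixture generators.
#'
#' @param chains list of chains, each `list(id =, residues = list(...))`;
#'   each residue is `list(number, icode, name, one_letter, atoms)` with
#'   `atoms` an n x 3 matrix whose rownames are atom names.
#' @return object of class `structure3d`.
#' @export
new_structure <- function(chains) {
  structure(list(chains = chains), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", length(x$chains), " chain(s)\n", sep = "")
  for (ch in x$chains) {
    cat("  chain ", ch$id, ": ", length(ch$residues), " residues\n", sep = "")
  }
  invisible(x)
}

chain_by_id <- function(s, chain) {
  ids <- vapply(s$chains, `[[`, "", "id")
  k <- match(chain, ids)
  if (is.na(k)) stop("no chain with id '", chain, "'")
  s$chains[[k]]
}

chain_sequence <- function(ch) {
  paste(vapply(ch$residues, `[[`, "", "one_letter"), collapse = "")
}

# ---- PDB ------------------------------------------------------------------

parse_pdb_lines <- function(lines) {
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    tag <- substr(ln, 1, 6)
    if (tag == "ENDMDL") break  # first model only
    if (tag != "ATOM  ") next   # HETATM / waters dropped
    if (nchar(ln) < 54) stop("PDB parse error at line ", i,
                             ": ATOM record shorter than coordinate fields")
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    num <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (any(is.na(c(x, y, z))) || is.na(num)) {
      stop("PDB parse error at line ", i, ": malformed ATOM record")
    }
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    bf <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    recs[[length(recs) + 1]] <- list(
      atom = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      num = num,
      icode = trimws(substr(ln, 27, 27)),
      pos = c(x, y, z),
      occ = if (is.na(occ)) 1 else occ,
      bf = if (is.na(bf)) 0 else bf
    )
  }
  recs
}

# ---- minimal mmCIF atom_site reader ---------------------------------------

cif_tokens <- function(ln) {
  toks <- character(0)
  i <- 1L
  n <- nchar(ln)
  while (i <= n) {
    ch <- substr(ln, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(ln, j, j) != ch) j <- j + 1L
      toks <- c(toks, substr(ln, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(ln, j, j) %in% c(" ", "\t")) j <- j + 1L
      toks <- c(toks, substr(ln, i, j - 1L))
      i <- j
    }
  }
  toks
}

parse_mmcif_atom_site <- function(lines) {
  # locate the atom_site loop
  fields <- character(0)
  rows <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[[i]])) {
      j <- i + 1L
      f <- character(0)
      while (j <= n && grepl("^\\s*_atom_site\\.", lines[[j]])) {
        f <- c(f, sub("^\\s*_atom_site\\.([^ ]+)\\s*$", "\\1", lines[[j]]))
        j <- j + 1L
      }
      if (length(f) > 0) {
        fields <- f
        while (j <= n) {
          ln <- lines[[j]]
          if (grepl("^\\s*(#|loop_|_[A-Za-z])", ln) || grepl("^\\s*$", ln)) break
          rows[[length(rows) + 1L]] <- cif_tokens(ln)
          j <- j + 1L
        }
        break
      }
    }
    i <- i + 1L
  }
  if (length(fields) == 0) stop("mmCIF parse error: no _atom_site loop found")
  list(fields = fields, rows = rows)
}

cif_get <- function(row, fields, name, alt = NULL) {
  k <- match(name, fields)
  if (is.na(k) && !is.null(alt)) k <- match(alt, fields)
  if (is.na(k)) return(NA_character_)
  row[[k]]
}

mmcif_records <- function(lines) {
  at <- parse_mmcif_atom_site(lines)
  recs <- list()
  for (r in at$rows) {
    if (length(r) != length(at$fields)) {
      stop("mmCIF parse error: atom_site row with ", length(r),
           " values for ", length(at$fields), " fields")
    }
    grp <- cif_get(r, at$fields, "group_PDB")
    if (!is.na(grp) && grp != "ATOM") next
    model <- cif_get(r, at$fields, "pdbx_PDB_model_num")
    if (!is.na(model) && model != "" && model != "." && model != "1") next
    icode <- cif_get(r, at$fields, "pdbx_PDB_ins_code")
    if (is.na(icode) || icode %in% c(".", "?")) icode <- ""
    alt <- cif_get(r, at$fields, "label_alt_id")
    if (is.na(alt) || alt %in% c(".", "?")) alt <- " "
    occ <- suppressWarnings(as.numeric(cif_get(r, at$fields, "occupancy")))
    num <- suppressWarnings(as.integer(
      cif_get(r, at$fields, "auth_seq_id", "label_seq_id")))
    xyz <- suppressWarnings(as.numeric(c(
      cif_get(r, at$fields, "Cartn_x"),
      cif_get(r, at$fields, "Cartn_y"),
      cif_get(r, at$fields, "Cartn_z"))))
    if (any(is.na(xyz)) || is.na(num)) {
      stop("mmCIF parse error: malformed atom_site row")
    }
    recs[[length(recs) + 1L]] <- list(
      atom = cif_get(r, at$fields, "label_atom_id", "auth_atom_id"),
      altloc = alt,
      resname = cif_get(r, at$fields, "label_comp_id"),
      chain = cif_get(r, at$fields, "auth_asym_id", "label_asym_id"),
      num = num, icode = icode, pos = xyz,
      occ = if (is.na(occ)) 1 else occ, bf = 0
    )
  }
  recs
}

# ---- shared record -> Structure assembly ----------------------------------

records_to_structure <- function(recs) {
  if (length(recs) == 0) stop("no ATOM records found")
  water <- vapply(recs, function(r) r$resname %in% c("HOH", "WAT"), TRUE)
  recs <- recs[!water]
  amino <- vapply(recs, function(r) r$resname %in% names(AA1), TRUE)
  recs <- recs[amino]
  if (length(recs) == 0) stop("no polymer ATOM records found")

  chains <- list()
  key_chain <- vapply(recs, `[[`, "", "chain")
  for (cid in unique(key_chain)) {
    crecs <- recs[key_chain == cid]
    rkey <- vapply(crecs, function(r) paste(r$num, r$icode, sep = "|"), "")
    residues <- list()
    for (rk in unique(rkey)) {
      rr <- crecs[rkey == rk]
      # altloc resolution: per atom name keep highest occupancy, ties by letter
      anames <- vapply(rr, `[[`, "", "atom")
      keep <- list()
      for (an in unique(anames)) {
        cand <- rr[anames == an]
        occs <- vapply(cand, `[[`, 0, "occ")
        alts <- vapply(cand, `[[`, "", "altloc")
        ord <- order(-occs, alts)
        keep[[an]] <- cand[[ord[1]]]
      }
      atoms <- do.call(rbind, lapply(keep, `[[`, "pos"))
      rownames(atoms) <- names(keep)
      residues[[length(residues) + 1L]] <- new_residue(
        number = keep[[1]]$num, icode = keep[[1]]$icode,
        name = keep[[1]]$resname, atoms = atoms,
        occupancy = vapply(keep, `[[`, 0, "occ"),
        bfactor = vapply(keep, `[[`, 0, "bf"))
    }
    complete <- vapply(residues, function(r) {
      all(BACKBONE_ATOMS %in% rownames(r$atoms))
    }, TRUE)
    if (!any(complete)) {
      warning("chain '", cid, "' has no residue with a complete backbone; ",
              "dropped")
      next
    }
    residues <- residues[complete]
    chains[[length(chains) + 1L]] <- list(id = cid, residues = residues)
  }
  if (length(chains) == 0) stop("no chain with complete backbone residues")
  new_structure(chains)
}

#' Read a structure file
#'
#' Reads the first model of a PDB or minimal mmCIF (atom_site loop) file.
#' HETATM records and waters are dropped; alternate locations are resolved to
#' the highest-occupancy conformer (ties broken by altloc letter); residues
#' lacking any of N, CA, C, O are dropped and chains with no complete
#' backbone residue are dropped with a warning.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"mmcif"`; default guessed from the extension.
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  dialect <- match.arg(dialect, c("pdb", "mmcif"))
  lines <- readLines(path, warn = FALSE)
  recs <- if (dialect == "pdb") parse_pdb_lines(lines) else mmcif_records(lines)
  records_to_structure(recs)
}

#' Write a structure as PDB
#'
#' @param s a `structure3d` object with finite coordinates.
#' @param path output file path.
#' @param dialect only `"pdb"` is supported for writing.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path, dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  out <- character(0)
  serial <- 1L
  for (ch in s$chains) {
    for (res in ch$residues) {
      if (res$number > 9999 || res$number < -999) {
        stop("residue number ", res$number, " out of PDB range")
      }
      atoms <- res$atoms
      if (any(!is.finite(atoms))) {
        stop("non-finite coordinate in residue ", res$number,
             " of chain ", ch$id)
      }
      for (k in seq_len(nrow(atoms))) {
        an <- rownames(atoms)[k]
        name_field <- if (nchar(an) >= 4) substr(an, 1, 4)
                      else sprintf(" %-3s", an)
        occ <- if (!is.null(res$occupancy)) res$occupancy[[k]] else 1
        bf <- if (!is.null(res$bfactor)) res$bfactor[[k]] else 0
        out <- c(out, sprintf(
          "ATOM  %5d %s %-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name_field, res$name, ch$id, res$number,
          ifelse(res$icode == "", " ", res$icode),
          atoms[k, 1], atoms[k, 2], atoms[k, 3], occ, bf,
          atom_element(an)))
        serial <- serial + 1L
      }
    }
    out <- c(out, sprintf("TER   %5d      %-3s %s", serial %% 100000L,
                          ch$residues[[length(ch$residues)]]$name, ch$id))
    serial <- serial + 1L
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

# ---- FASTA alignments -----------------------------------------------------

#' Read a multiple sequence alignment in FASTA format
#'
#' Row 0 is the target and rows 1.. are templates by convention. Sequences
#' are uppercased; all rows must have equal length.
#'
#' @param path FASTA file with >= 2 gapped records (gap character `-`).
#' @return object of class `alignment`: list with `ids`, `rows` (character
#'   vector) and `attachments` (per-row, filled by [attach_view()]).
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      ids <- c(ids, trimws(substring(ln, 2)))
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else if (!is.null(cur)) {
      seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", ln))
    }
  }
  if (length(seqs) < 2) stop("alignment needs at least 2 records")
  if (any(nchar(seqs) == 0)) stop("empty alignment record")
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment rows have unequal lengths: ",
         paste(nchar(seqs), collapse = ", "))
  }
  seqs <- toupper(seqs)
  if (any(grepl("[^A-Z-]", seqs))) stop("alignment contains invalid characters")
  structure(list(ids = ids, rows = seqs,
                 attachments = vector("list", length(seqs))),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> ", length(x$rows), " rows x ", nchar(x$rows[1]),
      " columns\n", sep = "")
  invisible(x)
}

#' Attach a structure chain to an alignment row
#'
#' The ungapped row sequence must match the chain's one-letter sequence
#' exactly or as a contiguous subsequence with a unique offset. On success a
#' column-to-residue-index map (1-based residue indices, NA at gaps) is stored
#' for the row.
#'
#' @param aln an `alignment`.
#' @param row row index (1-based).
#' @param s a `structure3d`.
#' @param chain chain id within `s`.
#' @return the alignment with the attachment recorded.
#' @export
attach_view <- function(aln, row, s, chain) {
  stopifnot(inherits(aln, "alignment"))
  if (row < 1 || row > length(aln$rows)) stop("row index out of range")
  ch <- chain_by_id(s, chain)
  chain_seq <- chain_sequence(ch)
  row_chars <- strsplit(aln$rows[[row]], "")[[1]]
  ungapped <- paste(row_chars[row_chars != "-"], collapse = "")
  nl <- nchar(ungapped)
  nc <- nchar(chain_seq)
  if (nl > nc) {
    stop("row sequence (", nl, " aa) longer than chain (", nc, " aa)")
  }
  hits <- integer(0)
  for (off in 0:(nc - nl)) {
    if (substr(chain_seq, off + 1, off + nl) == ungapped) hits <- c(hits, off)
  }
  if (length(hits) == 0) {
    # report first mismatch at offset 0 for diagnostics
    a <- strsplit(ungapped, "")[[1]]
    b <- strsplit(substr(chain_seq, 1, nl), "")[[1]]
    k <- which(a != b)[1]
    stop("row ", row, " does not match chain '", chain, "': first mismatch ",
         "at ungapped position ", k, " ('", a[k], "' vs '", b[k], "')")
  }
  if (length(hits) > 1) {
    stop("ambiguous attachment: row matches chain at offsets ",
         paste(hits, collapse = ", "))
  }
  col_map <- rep(NA_integer_, length(row_chars))
  col_map[row_chars != "-"] <- hits[1] + seq_len(nl)
  aln$attachments[[row]] <- list(structure = s, chain = chain,
                                 col_map = col_map)
  aln
}
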
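# Shared helpers: tiny hand-written file fixtures (built in code), an
# independent quaternion superposition oracle and a random rotamer-graph
# generator.

write_mini_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   CYS A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  CYS A   2       3.970   2.846   0.000  1.00  0.00           C",
    "ATOM      7  C   CYS A   2       5.486   2.705   0.000  1.00  0.00           C",
    "ATOM      8  O   CYS A   2       6.009   1.589   0.000  1.00  0.00           O",
    "ATOM      9  N   ASP A   3       6.191   3.832   0.000  1.00  0.00           N",
    "ATOM     10  CA  ASP A   3       7.646   3.852   0.000  1.00  0.00           C",
    "ATOM     11  C   ASP A   3       8.197   5.272   0.000  1.00  0.00           C",
    "ATOM     12  O   ASP A   3       7.439   6.242   0.000  1.00  0.00           O",
    "TER      13      ASP A",
    "END")
  writeLines(lines, path)
  path
}

write_mini_mmcif <- function(path = tempfile(fileext = ".cif")) {
  pdb <- readLines(write_mini_pdb())
  rows <- character(0)
  serial <- 0
  for (ln in pdb) {
    if (!startsWith(ln, "ATOM")) next
    serial <- serial + 1
    rows <- c(rows, sprintf(
      "ATOM %d %s . %s A %d ? %s %s %s 1.00 0.00 1",
      serial, trimws(substr(ln, 13, 16)), trimws(substr(ln, 18, 20)),
      as.integer(substr(ln, 23, 26)),
      trimws(substr(ln, 31, 38)), trimws(substr(ln, 39, 46)),
      trimws(substr(ln, 47, 54))))
  }
  writeLines(c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    rows, "#"), path)
  path
}

write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  out <- character(0)
  for (nm in names(records)) out <- c(out, paste0(">", nm), records[[nm]])
  writeLines(out, path)
  path
}

# independent superposition oracle: Horn's quaternion method
quaternion_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

random_rotamer_graph <- function(seed, np_max = 8, k_max = 5,
                                 p_edge = 0.5) {
  set.seed(seed)
  np <- sample(2:np_max, 1)
  ks <- sample(1:k_max, np, replace = TRUE)
  self <- lapply(ks, function(k) round(stats::rnorm(k), 3))
  edges <- list()
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      if (stats::runif(1) < p_edge) {
        edges[[length(edges) + 1]] <- list(
          i = i, j = j,
          m = matrix(round(stats::rnorm(ks[i] * ks[j]), 3), ks[i], ks[j]))
      }
    }
  }
  rotamer_graph(self, edges)
}

# enumerate all assignments and energies (independent of solve_brute_force)
enumerate_energies <- function(g) {
  ks <- vapply(g$self, length, 0L)
  grid <- as.matrix(do.call(expand.grid, lapply(ks, seq_len)))
  E <- apply(grid, 1, function(a) graph_energy(g, a))
  list(grid = grid, E = E)
}

# compact helix-loop-helix backbone structure without sidechains
make_hlh_structure <- function(seed = 4, n1 = 8, nc = 10, n2 = 8,
                               coil_phi = NULL, coil_psi = NULL) {
  deg <- pi / 180
  set.seed(seed)
  if (is.null(coil_phi)) coil_phi <- stats::runif(nc, -150, -60)
  if (is.null(coil_psi)) coil_psi <- stats::runif(nc, 80, 170)
  n <- n1 + nc + n2
  sq <- paste(sample(setdiff(homodel:::AA20, c("P", "G")), n, TRUE),
              collapse = "")
  phi <- c(rep(-57, n1), coil_phi, rep(-57, n2)) * deg
  psi <- c(rep(-47, n1), coil_psi, rep(-47, n2)) * deg
  backbone_to_structure(backbone_from_torsions(sq, phi, psi))
}

structure_seq <- function(s, chain = 1) {
  paste(vapply(s$chains[[chain]]$residues, `[[`, "", "one_letter"),
        collapse = "")
}

# alignment fixture: target/template rows attached to a template structure
attached_alignment <- function(target_row, template_row, tpl, chain = "A") {
  f <- write_fasta(list(target = target_row, template = template_row))
  attach_view(read_fasta_alignment(f), 2, tpl, chain)
}
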
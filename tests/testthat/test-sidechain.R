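# Rotamer library, rotamer construction, energies, disulfides and the
# sidechain reconstruction pipeline.

test_that("bbdep library parsing: renormalization, sorting, errors", {
  f <- tempfile()
  writeLines(c(
    "# comment",
    "SER  -60  -40  10  0.6  62 0 0 0  8 10 10 10",
    "SER  -60  -40  10  0.3 -65 0 0 0  8 10 10 10",
    "SER  -60  -40  10  0.3 180 0 0 0  8 10 10 10"), f)
  lib <- read_bbdep_library(f)
  es <- lib$entries[["S|-60|-40"]]
  expect_length(es, 3)
  p <- vapply(es, `[[`, 0, "probability")
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], 0.5)  # 0.6 / 1.2 renormalized

  # 17-column Dunbrack-style rows parse too
  writeLines(paste("VAL -60 -40 10 1 2 0 0 0.7 175 0 0 0 7 0 0 0"), f)
  lib2 <- read_bbdep_library(f)
  expect_equal(lib2$entries[["V|-60|-40"]][[1]]$chi, 175)

  writeLines("XXX -60 -40 10 0.6 62 0 0 0 8 10 10 10", f)
  expect_error(read_bbdep_library(f), "line 1")
  writeLines("SER -60 -40 10 0.6 bad 0 0 0 8 10 10 10", f)
  expect_error(read_bbdep_library(f), "line 1")
})

test_that("the bundled example bbdep file parses", {
  f <- system.file("extdata", "example_bbdep.txt", package = "homodel")
  lib <- read_bbdep_library(f)
  expect_setequal(names(lib$entries),
                  c("S|-60|-40", "L|-60|-40", "V|-120|130"))
  expect_equal(vapply(lib$entries[["S|-60|-40"]], `[[`, 0, "probability"),
               c(0.55, 0.30, 0.15), tolerance = 1e-9)
})

test_that("library write/read round trip preserves parameters", {
  f <- tempfile()
  writeLines(c(
    "LEU  -60  -40  10  0.7  -65  175 0 0  8 9 10 10",
    "LEU  -60  -40  10  0.3  180   65 0 0  8 9 10 10"), f)
  lib <- read_bbdep_library(f)
  f2 <- tempfile()
  write_rotamer_library(lib, f2)
  lib2 <- read_bbdep_library(f2)
  e1 <- lib$entries[[1]]
  e2 <- lib2$entries[[1]]
  for (k in seq_along(e1)) {
    expect_equal(e2[[k]]$probability, e1[[k]]$probability, tolerance = 1e-6)
    expect_equal(e2[[k]]$chi, e1[[k]]$chi, tolerance = 1e-6)
    expect_equal(e2[[k]]$sigma, e1[[k]]$sigma, tolerance = 1e-6)
  }
})

test_that("chi round trip holds for all 18 chi-bearing amino acids", {
  h <- make_ideal_helix(6, 1)
  frame <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ], cb = h$cb[3, ])
  set.seed(2)
  for (aa in names(homodel:::CHI_DEFS)) {
    for (rep_i in 1:3) {
      chi <- stats::runif(n_chi(aa), -179, 179)
      r <- build_rotamer(aa, frame, chi)
      got <- measure_chi(aa, homodel:::rotamer_chi_atoms(r))
      expect_lt(max(homodel:::circ_diff_deg(got, chi)), 1e-6)
    }
  }
  expect_error(build_rotamer("G", frame), "glycine")
  ala <- build_rotamer("A", frame, numeric(0))
  expect_equal(rownames(ala$atoms), "CB")
  expect_error(build_rotamer("S", frame, c(60, 60)), "chi angle")
})

test_that("rotamer groups respect coverage and FRM sub-rotamer counts", {
  f <- tempfile()
  writeLines(c(
    "SER -60 -40 10 0.70  62 0 0 0 8 10 10 10",
    "SER -60 -40 10 0.25 -65 0 0 0 8 10 10 10",
    "SER -60 -40 10 0.05 180 0 0 0 8 10 10 10"), f)
  lib <- read_bbdep_library(f)
  h <- make_ideal_helix(5, 1)
  frame <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ], cb = h$cb[3, ])
  phi <- -60 * pi / 180
  psi <- -40 * pi / 180
  expect_length(get_rotamer_group(lib, "S", phi, psi, frame,
                                  coverage = 0.9), 2)
  expect_length(get_rotamer_group(lib, "S", phi, psi, frame,
                                  coverage = 1.0), 3)
  frm <- get_rotamer_group(lib, "S", phi, psi, frame, mode = "FRM",
                           coverage = 0.5)
  expect_length(frm[[1]]$subs, 3)  # 1 + 2 * n_chi for SER
  expect_equal(frm[[1]]$subs[[1]]$chi, 62)
  # self energy carries -K ln p
  expect_equal(frm[[1]]$self_energy, -log(0.7), tolerance = 1e-9)
  expect_error(get_rotamer_group(lib, "W", phi, psi, frame), "entries")
})

test_that("pairwise and frame energies follow the piecewise-linear form", {
  h <- make_ideal_helix(12, 1, sequence = strrep("S", 12))
  frame_a <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ], cb = h$cb[3, ])
  frame_b <- list(n = h$n[9, ], ca = h$ca[9, ], c = h$c[9, ],
                  cb = h$cb[9, ])
  ra <- build_rotamer("S", frame_a, -65, res_id = 3)
  rb <- build_rotamer("S", frame_b, -65, res_id = 9)
  # far apart -> zero
  far <- rb
  far$atoms <- far$atoms + 50
  expect_equal(pairwise_energy(ra, far), 0)
  # coincident atoms -> at the ceiling
  co <- ra
  expect_gte(pairwise_energy(ra, co), 10)
  # brute-force sum oracle
  oracle <- 0
  for (a in seq_len(nrow(ra$atoms))) {
    for (b in seq_len(nrow(rb$atoms))) {
      d <- sqrt(sum((ra$atoms[a, ] - rb$atoms[b, ])^2))
      R <- homodel:::CLASH_RADII[[homodel:::atom_element(rownames(ra$atoms)[a])]] +
        homodel:::CLASH_RADII[[homodel:::atom_element(rownames(rb$atoms)[b])]]
      if (d < R) oracle <- oracle + clash_penalty(d, R)
    }
  }
  expect_equal(pairwise_energy(ra, rb), oracle, tolerance = 1e-12)

  # FRM with identical sub-rotamers degenerates to the rigid value
  fr <- build_flexible_rotamer("S", frame_a, -65, sigmas = 0, res_id = 3)
  expect_equal(pairwise_energy(fr, rb), pairwise_energy(ra, rb),
               tolerance = 1e-9)
  # FRM energy is bracketed by its sub-rotamer extremes
  fr2 <- build_flexible_rotamer("S", frame_a, -65, sigmas = 15, res_id = 3)
  subs_e <- vapply(fr2$subs, function(s) pairwise_energy(s, rb), 0)
  e <- pairwise_energy(fr2, rb)
  expect_gte(e, min(subs_e) - 1e-9)
  expect_lte(e, max(subs_e) + 1e-9)

  # frame energy mirrors pairwise with exclusions
  ftab <- list(pos = rb$atoms, elem = homodel:::atom_element(rownames(rb$atoms)),
               res = rep(9L, nrow(rb$atoms)),
               name = rownames(rb$atoms))
  expect_equal(frame_energy(ra, ftab), oracle, tolerance = 1e-12)
  # own residue excluded entirely
  ftab_self <- ftab
  ftab_self$res <- rep(3L, nrow(rb$atoms))
  expect_equal(frame_energy(ra, ftab_self), 0)
})

test_that("disulfide detection pairs greedily and deterministically", {
  # frames placed so the trans-trans rotamer combination sits at a chosen
  # SG-SG distance
  h <- make_ideal_helix(5, 1)
  frame_a <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ],
                  cb = h$cb[3, ])
  cys_at <- function(offset_from, d_target, res_id) {
    r0 <- build_rotamer("C", frame_a, 180, res_id = res_id)
    u <- c(1, 0.3, -0.2)
    u <- u / sqrt(sum(u^2))
    shift <- offset_from + d_target * u - r0$atoms["SG", ]
    fr <- lapply(frame_a, function(v) v + shift)
    list(pos = res_id,
         rotamers = list(build_rotamer("C", fr, 180, res_id = res_id)))
  }
  base <- build_rotamer("C", frame_a, 180, res_id = 1)
  sg0 <- base$atoms["SG", ]
  gA <- list(pos = 1, rotamers = list(base))
  gB <- cys_at(sg0, 2.05, 5)
  gC <- cys_at(sg0, 2.30, 9)
  pairs <- detect_disulfides(list(gA, gB))
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$sg_dist, 2.05, tolerance = 1e-6)

  # three mutually reachable cysteines: the greedy pick is the one closest
  # to 2.05 A, each cysteine used once, deterministic
  three <- list(gA, gB, gC)
  p1 <- detect_disulfides(three)
  p2 <- detect_disulfides(three)
  expect_identical(p1, p2)
  expect_equal(c(p1[[1]]$i, p1[[1]]$j), c(1, 2))
  used <- unlist(lapply(p1, function(p) c(p$i, p$j)))
  expect_equal(anyDuplicated(used), 0)

  # far-apart cysteines produce nothing
  gFar <- cys_at(sg0, 40, 13)
  expect_length(detect_disulfides(list(gA, gFar)), 0)
})

test_that("chi1_fraction counts circular differences and symmetric rings", {
  tp <- make_toy_protein(20, 4)
  expect_equal(chi1_fraction(tp, tp), 1.0)
  # rotate one chi-bearing residue's chi1 by 120 degrees
  ch <- tp$chains[[1]]
  k <- which(vapply(ch$residues, function(r) n_chi(r$one_letter) > 0,
                    TRUE))
  n_chi1 <- length(k)
  mod <- tp
  res <- ch$residues[[k[1]]]
  bb <- backbone_from_chain(tp, "A")
  i <- k[1]
  chi <- measure_chi(res$one_letter, res$atoms)
  chi[1] <- chi[1] + 120
  r_new <- build_rotamer(res$one_letter,
                         list(n = bb$n[i, ], ca = bb$ca[i, ], c = bb$c[i, ],
                              cb = bb$cb[i, ]), chi)
  bbat <- res$atoms[rownames(res$atoms) %in% c("N", "CA", "C", "O"), ]
  mod$chains[[1]]$residues[[i]]$atoms <- rbind(bbat, r_new$atoms)
  expect_equal(chi1_fraction(mod, tp), (n_chi1 - 1) / n_chi1)

  # a PHE ring flip (chi2 + 180) leaves chi1 correct
  h <- make_ideal_helix(5, 1, sequence = "AAFAA")
  s <- backbone_to_structure(h)
  fr <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ], cb = h$cb[3, ])
  r1 <- build_rotamer("F", fr, c(-65, 90))
  r2 <- build_rotamer("F", fr, c(-65, 270))
  s1 <- s
  s2 <- s
  bbat <- s$chains[[1]]$residues[[3]]$atoms
  s1$chains[[1]]$residues[[3]]$atoms <- rbind(bbat[1:4, ], r1$atoms)
  s2$chains[[1]]$residues[[3]]$atoms <- rbind(bbat[1:4, ], r2$atoms)
  expect_equal(chi1_fraction(s1, s2), 1.0)
})

test_that("count_clashing_sidechains flags interpenetrating residues", {
  h <- make_ideal_helix(10, 1)
  s <- backbone_to_structure(h)
  expect_equal(count_clashing_sidechains(s), 0)
  expect_equal(count_clashing_sidechains(s, factor = 0), 0)

  # two LEU placed on top of each other -> both flagged
  fr1 <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ], cb = h$cb[3, ])
  r1 <- build_rotamer("L", fr1, c(-65, 175))
  s2 <- backbone_to_structure(make_ideal_helix(10, 1,
                                               sequence = "AALAAAALAA"))
  bb3 <- s2$chains[[1]]$residues[[3]]$atoms
  bb8 <- s2$chains[[1]]$residues[[8]]$atoms
  s2$chains[[1]]$residues[[3]]$atoms <- rbind(bb3[1:4, ], r1$atoms)
  moved <- r1$atoms + matrix(c(0.3, 0, 0), nrow(r1$atoms), 3, byrow = TRUE)
  s2$chains[[1]]$residues[[8]]$atoms <- rbind(bb8[1:4, ], moved)
  expect_equal(count_clashing_sidechains(s2), 2)
  expect_error(count_clashing_sidechains(s2, sigma_table = c(C = 3.5)),
               "sigma table")
})

test_that("reconstruct_sidechains recovers native chi1 with a native-topped library", {
  aas <- c("R", "N", "D", "C", "Q", "E", "H", "I", "L", "K", "M", "F", "S",
           "T", "W", "Y", "V", "L", "I", "V")
  tp <- make_toy_protein(20, 1, sequence = paste(aas, collapse = ""))
  ch <- tp$chains[[1]]
  entries <- list()
  for (i in seq_along(ch$residues)) {
    res <- ch$residues[[i]]
    nch <- n_chi(res$one_letter)
    if (nch == 0 || !is.null(entries[[res$one_letter]])) next
    native <- measure_chi(res$one_letter, res$atoms)
    entries[[res$one_letter]] <- list(
      list(probability = 0.8, chi = native, sigma = rep(6, nch)),
      list(probability = 0.15, chi = native + c(120, rep(0, nch - 1)),
           sigma = rep(6, nch)),
      list(probability = 0.05, chi = native - c(120, rep(0, nch - 1)),
           sigma = rep(6, nch)))
  }
  lib <- homodel:::new_rotamer_library(entries, backbone_dependent = FALSE)
  stripped <- tp
  for (i in seq_along(ch$residues)) {
    at <- stripped$chains[[1]]$residues[[i]]$atoms
    stripped$chains[[1]]$residues[[i]]$atoms <-
      at[rownames(at) %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  }
  rec <- reconstruct_sidechains(stripped, lib, mode = "FRM")
  expect_equal(chi1_fraction(rec, tp), 1.0)
  expect_equal(count_clashing_sidechains(rec), 0)
  # an already-complete structure passes through unchanged
  expect_identical(reconstruct_sidechains(tp, lib), tp)
})
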
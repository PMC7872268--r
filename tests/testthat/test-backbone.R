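# BackboneList: coordinate synchronization, torsion edits, superposition,
# CB reconstruction.

test_that("torsion-built backbones reproduce their inputs", {
  set.seed(1)
  for (n in c(1, 2, 5, 17, 30)) {
    sq <- paste(sample(homodel:::AA20, n, TRUE), collapse = "")
    phi <- stats::runif(n, -pi, pi)
    psi <- stats::runif(n, -pi, pi)
    bb <- backbone_from_torsions(sq, phi, psi)
    if (n >= 2) {
      expect_lt(max(abs(bb$phi[-1] - phi[-1])), 1e-6)
      expect_lt(max(abs(bb$psi[-n] - psi[-n])), 1e-6)
    } else {
      expect_true(all(is.na(c(bb$phi, bb$psi))))
    }
    # peptide bonds inside the contract range
    if (n >= 2) {
      d <- vapply(seq_len(n - 1), function(i) {
        sqrt(sum((bb$n[i + 1, ] - bb$c[i, ])^2))
      }, 0)
      expect_true(all(d >= 1.2 & d <= 1.5))
    }
  }
  expect_error(backbone_from_torsions("AAA", c(1, 2), c(1, 2, 3)), "length")
})

test_that("backbone_from_chain measures torsions and rebuilds CB", {
  h <- make_ideal_helix(10, 1)
  s <- backbone_to_structure(h)
  bb <- backbone_from_chain(s, "A")
  expect_lt(max(abs(bb$phi[-1] + 57 * pi / 180)), 1 * pi / 180)
  expect_lt(max(abs(bb$psi[-10] + 47 * pi / 180)), 1 * pi / 180)

  one <- backbone_from_chain(backbone_to_structure(make_ideal_helix(1, 1)),
                             "A")
  expect_length(one$seq, 1)
  expect_true(is.na(one$phi[1]) && is.na(one$psi[1]))

  s_bad <- s
  at <- s_bad$chains[[1]]$residues[[3]]$atoms
  s_bad$chains[[1]]$residues[[3]]$atoms <- at[rownames(at) != "O", ]
  expect_error(backbone_from_chain(s_bad, "A"), "O")
})

test_that("set_torsion is a local rigid rotation", {
  bb <- backbone_from_torsions("AAAAAA", rep(pi, 6), rep(pi, 6))
  b2 <- set_torsion(bb, 3, "psi", 1.0)
  # upstream untouched bit-for-bit
  expect_identical(b2$n[1:3, ], bb$n[1:3, ])
  expect_identical(b2$ca[1:3, ], bb$ca[1:3, ])
  expect_identical(b2$c[1:3, ], bb$c[1:3, ])
  # downstream pairwise distances preserved
  down <- rbind(b2$n[4:6, ], b2$ca[4:6, ], b2$c[4:6, ])
  down0 <- rbind(bb$n[4:6, ], bb$ca[4:6, ], bb$c[4:6, ])
  expect_lt(max(abs(dist(down) - dist(down0))), 1e-9)
  expect_lt(abs(b2$psi[3] - 1.0), 1e-12)
  # identity and inverse
  expect_lt(max(abs(set_torsion(bb, 3, "psi", bb$psi[3])$ca - bb$ca)), 1e-9)
  b3 <- set_torsion(set_torsion(bb, 4, "phi", 0.5), 4, "phi", bb$phi[4])
  expect_lt(max(abs(b3$ca - bb$ca)), 1e-9)
  expect_error(set_torsion(bb, 1, "phi", 0), "undefined")
})

test_that("superpose matches the quaternion oracle", {
  set.seed(7)
  h <- make_ideal_helix(9, 2)
  expect_lt(superpose(h, h)$rmsd, 1e-9)
  # recover an arbitrary rigid transform
  R <- homodel:::rotation_about_axis(stats::rnorm(3), 1.3)
  moved <- transform_backbone(h, R, c(4, -2, 7))
  fit <- superpose(moved, h)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$rotation %*% R - diag(3))), 1e-9)
  # random perturbations vs independent quaternion implementation
  for (k in 1:100) {
    pert <- h
    pert$ca <- h$ca + matrix(stats::rnorm(27, 0, 0.5), 9, 3)
    expect_lt(abs(ca_rmsd(pert, h, superposed = TRUE) -
                    quaternion_rmsd(pert$ca, h$ca)), 1e-6)
  }
  expect_error(superpose(h, make_ideal_helix(5, 1)), "differ")
})

test_that("ca_rmsd distinguishes frames from conformations", {
  h1 <- make_ideal_helix(8, 3)
  h2 <- transform_backbone(h1, homodel:::rotation_about_axis(c(1, 1, 0), 0.8),
                           c(1, 2, 3))
  expect_gt(ca_rmsd(h1, h2, superposed = FALSE), 1)
  expect_lt(ca_rmsd(h1, h2, superposed = TRUE), 1e-9)
})

test_that("reconstruct_cb is tetrahedral, accurate and chirality-aware", {
  h <- make_ideal_helix(6, 1)
  cb <- reconstruct_cb(h$n[3, ], h$ca[3, ], h$c[3, ])
  expect_lt(abs(sqrt(sum((cb - h$ca[3, ])^2)) - 1.530), 1e-6)
  imp <- dihedral(h$n[3, ], h$ca[3, ], h$c[3, ], cb) * 180 / pi
  expect_lt(abs(imp + 122.5), 2)
  # reconstruction error against a stored CB
  expect_lt(sqrt(sum((cb - h$cb[3, ])^2)), 0.2)
  # three points carry no handedness: the construction pins L-chirality
  # (improper -122.5) in any frame, including a mirrored one
  mir <- function(v) v * c(-1, 1, 1)
  cb_m <- reconstruct_cb(mir(h$n[3, ]), mir(h$ca[3, ]), mir(h$c[3, ]))
  imp_m <- dihedral(mir(h$n[3, ]), mir(h$ca[3, ]), mir(h$c[3, ]), cb_m) *
    180 / pi
  expect_lt(abs(imp_m + 122.5), 2)
  expect_error(reconstruct_cb(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("glycine carries no CB", {
  bb <- backbone_from_torsions("AGA", rep(-1, 3), rep(2, 3))
  expect_true(is.na(bb$cb[2, 1]))
  expect_false(anyNA(bb$cb[c(1, 3), ]))
})
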
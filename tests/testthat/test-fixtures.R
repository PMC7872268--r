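# Fixture generators: determinism and structural sanity.

test_that("ideal helix has canonical rise and CA spacing", {
  h <- make_ideal_helix(10, 1)
  dca <- vapply(1:9, function(i) sqrt(sum((h$ca[i + 1, ] - h$ca[i, ])^2)),
                0)
  expect_true(all(abs(dca - 3.8) < 0.1))
  # rise per residue along the helix axis ~1.5 A
  axis <- prcomp(h$ca)$rotation[, 1]
  proj <- h$ca %*% axis
  expect_lt(abs(mean(diff(proj)) - 1.5), 0.2)
  expect_length(make_ideal_helix(1, 1)$seq, 1)
  expect_identical(make_ideal_helix(8, 3)$ca, make_ideal_helix(8, 3)$ca)
})

test_that("toy proteins are reproducible, seed-sensitive and clash-free", {
  a <- make_toy_protein(20, 1)
  b <- make_toy_protein(20, 1)
  expect_identical(a, b)
  c_ <- make_toy_protein(20, 2)
  expect_false(identical(structure_seq(a), structure_seq(c_)))
  expect_equal(count_clashing_sidechains(a), 0)
})

test_that("make_loop_case cuts a span and keeps the rest untouched", {
  tp <- make_toy_protein(24, 1)
  lc <- make_loop_case(tp, 12:15)
  expect_length(lc$mh$gaps, 1)
  expect_false(any(lc$mh$present[12:15]))
  bb <- backbone_from_chain(tp, "A")
  expect_identical(lc$mh$ca[1:11, ], bb$ca[1:11, ])
  expect_identical(lc$mh$ca[16:24, ], bb$ca[16:24, ])
  # re-inserting the reference closes with zero anchor RMSD
  L <- length(lc$reference$seq)
  res <- ccd_close(lc$reference,
                   rbind(lc$reference$n[1, ], lc$reference$ca[1, ],
                         lc$reference$c[1, ]),
                   rbind(lc$reference$n[L, ], lc$reference$ca[L, ],
                         lc$reference$c[L, ]))
  expect_equal(res$iterations, 0L)
  expect_error(make_loop_case(tp, 1:4), "interior")
})

test_that("decoy sets carry faithful RMSD labels across a sigma ladder", {
  tp <- make_toy_protein(24, 2)
  lc <- make_loop_case(tp, 11:14)
  decoys <- make_decoy_set(lc$reference, n = 15, seed = 3)
  expect_length(decoys, 15)
  # sigma 0 decoys are exact copies
  expect_equal(decoys[[1]]$rmsd, 0)
  # labels recomputed independently match
  L <- length(lc$reference$seq)
  inner <- 2:(L - 1)
  for (d in decoys) {
    rm2 <- sqrt(mean(rowSums((d$loop$ca[inner, , drop = FALSE] -
                                lc$reference$ca[inner, , drop = FALSE])^2)))
    expect_equal(d$rmsd, rm2, tolerance = 1e-9)
  }
  expect_gte(length(unique(round(vapply(decoys, `[[`, 0, "rmsd"), 6))), 3)
  expect_identical(make_decoy_set(lc$reference, 5, 9),
                   make_decoy_set(lc$reference, 5, 9))
})

test_that("make_mini_db wraps db building and self-retrieval holds", {
  md <- make_mini_db(list(make_toy_protein(30, 4)), lengths = 3:5)
  expect_gt(md$fdb$n_fragments, 0)
  expect_error(make_mini_db(list()), "at least one")
})

test_that("fixture rotamer library is normalized per amino acid", {
  lib <- fixture_rotamer_library()
  for (key in names(lib$entries)) {
    p <- vapply(lib$entries[[key]], `[[`, 0, "probability")
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(diff(p) <= 1e-9))
  }
})
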
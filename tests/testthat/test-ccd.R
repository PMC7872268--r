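# Cyclic coordinate descent loop closure.

ccd_case <- function(len, seed, sigma_deg = 10) {
  # native loop cut from a helix-coil fixture; torsions perturbed
  set.seed(seed)
  n <- len + 6
  sq <- paste(sample(homodel:::AA20, n, TRUE), collapse = "")
  phi <- stats::runif(n, -150, -50) * pi / 180
  psi <- stats::runif(n, -60, 160) * pi / 180
  bb <- backbone_from_torsions(sq, phi, psi)
  span <- 3:(len + 4)
  loop <- bb_subset(bb, span)
  L <- length(span)
  pert <- loop
  for (i in seq_len(L)) {
    if (!is.na(pert$phi[i])) {
      pert <- set_torsion(pert, i, "phi",
                          pert$phi[i] + stats::runif(1, -1, 1) * sigma_deg *
                            pi / 180)
    }
    if (!is.na(pert$psi[i]) && i < L) {
      pert <- set_torsion(pert, i, "psi",
                          pert$psi[i] + stats::runif(1, -1, 1) * sigma_deg *
                            pi / 180)
    }
  }
  n_anchor <- rbind(loop$n[1, ], loop$ca[1, ], loop$c[1, ])
  c_anchor <- rbind(loop$n[L, ], loop$ca[L, ], loop$c[L, ])
  list(loop = loop, pert = pert, n_anchor = n_anchor, c_anchor = c_anchor)
}

test_that("a native loop converges instantly", {
  cs <- ccd_case(6, 1, sigma_deg = 0)
  res <- ccd_close(cs$loop, cs$n_anchor, cs$c_anchor)
  expect_true(res$converged)
  expect_equal(res$iterations, 0L)
  expect_lt(res$anchor_rmsd, 1e-9)
})

test_that("perturbed loops re-close; first residue never moves; objective is monotone", {
  n_conv <- 0
  for (seed in 1:10) {
    cs <- ccd_case(4 + (seed %% 5), seed)
    res <- ccd_close(cs$pert, cs$n_anchor, cs$c_anchor)
    if (res$converged) n_conv <- n_conv + 1
    first <- rbind(res$loop$n[1, ], res$loop$ca[1, ], res$loop$c[1, ])
    expect_lt(max(abs(first - cs$n_anchor)), 1e-9)
    expect_true(all(diff(res$trace) <= 1e-9))
  }
  expect_gte(n_conv, 9)
})

test_that("geometrically impossible closures report failure, not an error", {
  cs <- ccd_case(4, 3, sigma_deg = 0)
  far <- cs$c_anchor + 100  # beyond any extension of a 6-residue loop
  res <- ccd_close(cs$pert, cs$n_anchor, far, max_iter = 50)
  expect_false(res$converged)
  expect_gt(res$anchor_rmsd, 1)
})

test_that("short loops are rejected", {
  cs <- ccd_case(4, 4)
  expect_error(ccd_close(bb_subset(cs$loop, 1:2), cs$n_anchor, cs$c_anchor),
               "at least 3")
})
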
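# Statistical potentials, scoring environment and scorers.

toy_env <- function(n = 30, seed = 2) {
  tp <- make_toy_protein(n, seed)
  bb <- backbone_from_chain(tp, "A")
  sdb <- db_add_chain(db_new(), "a", "A", bb)$db
  env <- env_set(env_new(paste(bb$seq, collapse = "")), bb, seq_len(n))
  list(bb = bb, env = env, pots = train_potentials(sdb), n = n)
}

test_that("inverse Boltzmann: uniform counts give zero energies", {
  obs <- matrix(250, 6, 12)
  expect_lt(max(abs(inverse_boltzmann(obs))), 1e-12)
  # empty table does not blow up
  expect_true(all(inverse_boltzmann(matrix(0, 2, 3)) == 0))
})

test_that("inverse Boltzmann recovers a Boltzmann density up to a constant", {
  set.seed(3)
  nb <- 14
  p <- exp(-(seq_len(nb) - 7)^2 / 8)
  p <- p / sum(p)
  # one Boltzmann-sampled context against a dominant uniform reference
  obs <- rbind(ctx = as.vector(stats::rmultinom(1, 1e5, p)),
               bulk = rep(5e6 / nb, nb))
  E <- inverse_boltzmann(obs)
  rec <- E[1, ] - mean(E[1, ])
  want <- -log(p) - mean(-log(p))
  expect_lt(sqrt(mean((rec - want)^2)), 0.1)
})

test_that("training on a single-chain db yields finite tables", {
  te <- toy_env()
  for (nm in c("cbeta", "reduced", "torsion", "cb_packing")) {
    expect_true(all(is.finite(te$pots[[nm]]$table)))
  }
  expect_error(train_potentials(db_new()), "empty")
})

test_that("env_set / env_clear are inverse and match a brute-force scan", {
  te <- toy_env()
  env0 <- env_new(paste(te$bb$seq, collapse = ""))
  env1 <- env_set(env0, bb_subset(te$bb, 5:10), 5:10)
  env2 <- env_clear(env1, 5:10)
  expect_identical(env2$set, env0$set)
  expect_true(all(is.na(env2$coords$ca[5:10, ])))
  # clearing an already-clear range is a no-op
  expect_identical(env_clear(env2, 5:10)$set, env2$set)
  expect_error(env_set(env0, bb_subset(te$bb, 1:2), 98:99), "bounds")

  # neighbour queries equal brute force after random set/clear churn
  set.seed(8)
  env <- env0
  for (k in 1:100) {
    span <- sort(sample(te$n, 2))
    idx <- span[1]:span[2]
    if (stats::runif(1) < 0.5) {
      env <- env_set(env, bb_subset(te$bb, idx), idx)
    } else {
      env <- env_clear(env, idx)
    }
  }
  pts <- te$bb$ca[c(3, 12, 25), ]
  for (r in 1:3) {
    nb <- env_neighbors(env, pts[r, ], 8)
    # oracle: scan every set atom
    cnt <- 0
    for (i in which(env$set)) {
      for (a in homodel:::ENV_ATOMS) {
        p <- env$coords[[a]][i, ]
        if (!is.na(p[1]) && sqrt(sum((p - pts[r, ])^2)) <= 8) cnt <- cnt + 1
      }
    }
    expect_equal(nrow(nb), cnt)
  }
})

test_that("every scorer equals its loop-based brute-force oracle", {
  te <- toy_env()
  env <- te$env
  bb <- te$bb
  pots <- te$pots
  n <- te$n
  cb_of <- function(i) if (is.na(bb$cb[i, 1])) bb$ca[i, ] else bb$cb[i, ]
  for (range in list(5:7, 12:16, 1:30)) {
    # cbeta
    s <- 0
    for (i in range) for (j in 1:n) {
      if (abs(i - j) < 4 || (j %in% range && j <= i)) next
      s <- s + homodel:::pair_energy_lookup(
        pots$cbeta, bb$seq[i], bb$seq[j],
        sqrt(sum((cb_of(i) - cb_of(j))^2)))
    }
    expect_equal(score_segment(env, range, "cbeta", pots), s / length(range),
                 tolerance = 1e-12)
    # reduced
    s <- 0
    for (i in range) for (j in 1:n) {
      if (abs(i - j) < 4 || (j %in% range && j <= i)) next
      vi <- cb_of(i) - bb$ca[i, ]
      vj <- cb_of(j) - bb$ca[j, ]
      ang <- acos(max(-1, min(1, sum(vi * vj) /
                                sqrt(sum(vi^2) * sum(vj^2)))))
      s <- s + homodel:::pair_energy_lookup(
        pots$reduced, bb$seq[i], bb$seq[j],
        sqrt(sum((bb$ca[i, ] - bb$ca[j, ])^2)), ang)
    }
    expect_equal(score_segment(env, range, "reduced", pots),
                 s / length(range), tolerance = 1e-12)
    # cb_packing
    s <- 0
    for (i in range) {
      cnt <- 0
      for (j in setdiff(1:n, i)) {
        if (sqrt(sum((cb_of(i) - cb_of(j))^2)) <= 10) cnt <- cnt + 1
      }
      s <- s + pots$cb_packing$table[homodel:::aa_index(bb$seq[i]),
                                     min(cnt, 30) + 1]
    }
    expect_equal(score_segment(env, range, "cb_packing", pots),
                 s / length(range), tolerance = 1e-12)
  }
  # determinism
  expect_identical(score_segment(env, 5:9, "clash", pots),
                   score_segment(env, 5:9, "clash", pots))
  expect_error(score_segment(env, 5:9, "nonsense", pots), "unknown")
  env_part <- env_clear(env, 7)
  expect_error(score_segment(env_part, 5:9, "cbeta", pots), "unset")
})

test_that("clash: boundary exact, non-negative, monotone in distance", {
  # two isolated CB atoms at exactly r_i + r_j -> zero
  sq <- "AA"
  bb <- backbone_from_torsions(sq, rep(pi, 2), rep(pi, 2))
  expect_equal(clash_penalty(3.2, 3.2), 0)
  expect_equal(clash_penalty(0.8254 * 3.2, 3.2), 10)
  d <- seq(0.1, 4, 0.05)
  expect_true(all(diff(clash_penalty(d, 3.2)) <= 0))
  expect_true(all(clash_penalty(d, 3.2) >= 0))
})

test_that("scores are invariant under rigid transforms of the environment", {
  te <- toy_env()
  set.seed(11)
  R <- homodel:::rotation_about_axis(stats::rnorm(3), 0.7)
  bbT <- transform_backbone(te$bb, R, c(5, -3, 2))
  envT <- env_set(env_new(paste(te$bb$seq, collapse = "")), bbT, 1:te$n)
  for (k in c("cbeta", "cb_packing", "clash", "hbond", "torsion",
              "reduced")) {
    expect_equal(score_segment(envT, 10:14, k, te$pots),
                 score_segment(te$env, 10:14, k, te$pots),
                 tolerance = 1e-9)
  }
})

test_that("constraint scorer applies user penalties on CA/CB distances", {
  te <- toy_env()
  d_true <- sqrt(sum((te$bb$ca[5, ] - te$bb$ca[20, ])^2))
  cons <- list(list(i = 5, j = 20, atoms = "ca",
                    fn = function(d) (d - d_true)^2))
  expect_equal(score_segment(te$env, 5:5, "constraint",
                             params = list(constraints = cons)), 0)
  cons2 <- list(list(i = 5, j = 20, atoms = "ca", fn = function(d) d))
  expect_equal(score_segment(te$env, 5:5, "constraint",
                             params = list(constraints = cons2)), d_true)
})

test_that("combine_scores is an exact weighted sum", {
  sc <- c(a = 1.5, b = -2, c = 0.25)
  expect_equal(combine_scores(sc, c(b = 1)), -2)
  expect_equal(combine_scores(sc, c(a = 0, b = 0, c = 0)), 0)
  set.seed(5)
  w <- stats::rnorm(3)
  names(w) <- names(sc)
  expect_equal(combine_scores(sc, w), sum(w * sc))
  expect_error(combine_scores(sc, c(zz = 1)), "missing")
})

test_that("fit_weights recovers exact and noisy linear models", {
  set.seed(6)
  X <- matrix(stats::rnorm(200), 50, 4,
              dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  # score1 == rmsd exactly, others noise
  w <- fit_weights(X, X[, 1])
  expect_lt(max(abs(w - c(1, 0, 0, 0))), 1e-9)
  # duplicated decoys give the same weights
  expect_equal(fit_weights(rbind(X, X), c(X[, 1], X[, 1])), w)
  # known weights + small noise
  beta <- c(2, -1, 0.5, 3)
  y <- as.numeric(X %*% beta + stats::rnorm(50, 0, 0.01))
  w2 <- fit_weights(X, y)
  expect_lt(max(abs(w2 - beta) / abs(beta)), 0.05)
  # rank-deficient design warns and still returns
  X2 <- X
  X2[, 4] <- X2[, 3]
  expect_warning(fit_weights(X2, y), "rank-deficient")
  expect_error(fit_weights(X[1:5, ], X[1:5, 1]), "at least 10")
})
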
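# Rotamer-graph packing solvers.

test_that("brute force: single position, additive graphs, tie-breaking", {
  g1 <- rotamer_graph(list(c(3, 1, 2)))
  expect_equal(solve_brute_force(g1)$assignment, 2L)
  # fully additive graph decomposes into independent argmins
  g2 <- rotamer_graph(list(c(2, 0), c(1, 5), c(0.5, -1)))
  sol <- solve_brute_force(g2)
  expect_equal(sol$assignment, c(2L, 1L, 2L))
  expect_equal(sol$energy, 0 + 1 - 1)
  # ties resolved lexicographically
  g3 <- rotamer_graph(list(c(0, 0), c(0, 0)))
  expect_equal(solve_brute_force(g3)$assignment, c(1L, 1L))
  g_big <- rotamer_graph(rep(list(rep(0, 10)), 8))
  expect_error(solve_brute_force(g_big), "too large")
})

test_that("Goldstein DEE removes dominated rotamers and preserves the optimum", {
  # dominated rotamer in every term -> removed
  g <- rotamer_graph(list(c(0, 5), c(0, 0)),
                     list(list(i = 1, j = 2,
                               m = matrix(c(0, 0, 2, 2), 2, 2,
                                          byrow = TRUE))))
  d <- dee_goldstein(g)
  expect_equal(d$kept[[1]], 1L)
  # all-equal energies: nothing removed
  g_eq <- rotamer_graph(list(c(1, 1), c(1, 1)))
  expect_equal(lengths(dee_goldstein(g_eq)$kept), c(2L, 2L))
  # optimum preservation on random instances
  for (seed in 1:200) {
    g <- random_rotamer_graph(seed, np_max = 6, k_max = 4)
    bf <- solve_brute_force(g)
    d <- dee_goldstein(g)
    expect_equal(solve_brute_force(d$graph)$energy, bf$energy,
                 tolerance = 1e-12)
  }
})

test_that("edge decomposition removes separable edges within tolerance", {
  a <- c(1, 2, 3)
  b <- c(0.5, -1)
  M <- outer(a, b, `+`)
  g <- rotamer_graph(list(rep(0, 3), rep(0, 2)),
                     list(list(i = 1, j = 2, m = M)))
  dec <- edge_decompose(g, 0)
  expect_equal(dec$removed, 1L)
  # all assignment energies reproduced exactly
  for (r in 1:3) for (s in 1:2) {
    expect_equal(graph_energy(dec$graph, c(r, s)), M[r, s],
                 tolerance = 1e-12)
  }
  # a genuinely coupled matrix survives eps = 0
  M2 <- M
  M2[1, 1] <- M2[1, 1] + 1
  g2 <- rotamer_graph(list(rep(0, 3), rep(0, 2)),
                      list(list(i = 1, j = 2, m = M2)))
  expect_equal(edge_decompose(g2, 0)$removed, 0L)
  # random graphs: optimum after decomposition within eps * |removed|
  for (seed in 1:50) {
    g <- random_rotamer_graph(seed + 400)
    eps <- 0.3
    dec <- edge_decompose(g, eps)
    e_orig <- solve_brute_force(g)$energy
    e_dec <- solve_brute_force(dec$graph)$energy
    expect_lte(abs(e_dec - e_orig), eps * dec$removed + 1e-9)
  }
})

test_that("treepack equals brute force on random sparse graphs", {
  # chain topology has width 1
  g_path <- rotamer_graph(
    list(c(0, 1), c(2, 0), c(1, 3)),
    list(list(i = 1, j = 2, m = matrix(c(1, 0, 0, 1), 2, 2)),
         list(i = 2, j = 3, m = matrix(c(0, 2, 1, 0), 2, 2))))
  expect_equal(solve_treepack(g_path)$energy,
               solve_brute_force(g_path)$energy)
  # disconnected components solve independently
  g_disc <- rotamer_graph(list(c(1, 0), c(0, 2), c(5, 3)))
  expect_equal(solve_treepack(g_disc)$energy, 0 + 0 + 3)
  for (seed in 1:200) {
    g <- random_rotamer_graph(seed + 2000)
    expect_equal(solve_treepack(g)$energy, solve_brute_force(g)$energy,
                 tolerance = 1e-12)
  }
  # width cap triggers a helpful error (complete graph on 4 positions)
  edges <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    edges[[length(edges) + 1]] <- list(i = i, j = j,
                                       m = matrix(stats::rnorm(4), 2, 2))
  }
  dense <- rotamer_graph(rep(list(c(0, 1)), 4), edges)
  expect_error(solve_treepack(dense, width_cap = 1), "width")
})

test_that("A* enumerates the exact window, sorted, optimum first", {
  # unique optimum, window 0 -> exactly one solution
  g <- rotamer_graph(list(c(0, 5), c(0, 5)))
  s0 <- solve_astar(g, 0)
  expect_length(s0$solutions, 1)
  expect_equal(s0$solutions[[1]]$assignment, c(1L, 1L))
  # infinite window on a 2x2 instance -> all 4, ascending
  sAll <- solve_astar(g, Inf)
  expect_length(sAll$solutions, 4)
  expect_true(all(diff(vapply(sAll$solutions, `[[`, 0, "energy")) >= 0))
  # solution cap flags truncation
  sCap <- solve_astar(g, Inf, max_solutions = 2)
  expect_true(sCap$truncated)
  # window enumeration equals an independent exhaustive enumeration
  for (seed in 1:50) {
    g <- random_rotamer_graph(seed + 3000, np_max = 6, k_max = 4)
    win <- 0.75
    got <- solve_astar(g, win)
    en <- enumerate_energies(g)
    want <- sort(en$E[en$E <= min(en$E) + win + 1e-12])
    have <- vapply(got$solutions, `[[`, 0, "energy")
    expect_equal(length(have), length(want))
    expect_equal(have, want, tolerance = 1e-9)
    expect_equal(have[1], solve_brute_force(g)$energy, tolerance = 1e-12)
  }
})

test_that("Monte Carlo finds optima reliably and is seed-deterministic", {
  hits <- 0
  n_runs <- 60
  for (seed in seq_len(n_runs)) {
    g <- random_rotamer_graph(seed + 5000, np_max = 6, k_max = 4)
    bf <- solve_brute_force(g)
    mc <- solve_monte_carlo(g, steps = 5000, T0 = 5, cool = 0.95,
                            seed = seed)
    if (abs(mc$energy - bf$energy) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
  # dominant rotamer per position: found in one sweep
  g_dom <- rotamer_graph(list(c(0, 9), c(0, 9), c(0, 9)))
  mc <- solve_monte_carlo(g_dom, steps = 3, T0 = 0.01, seed = 2)
  expect_equal(mc$energy, solve_brute_force(g_dom)$energy)
  # determinism
  g <- random_rotamer_graph(42)
  a <- solve_monte_carlo(g, steps = 500, seed = 7)
  b <- solve_monte_carlo(g, steps = 500, seed = 7)
  expect_identical(a, b)
})

test_that("sub-rotamer optimization never increases the rigid energy", {
  h <- make_ideal_helix(12, 1, sequence = strrep("S", 12))
  fr_of <- function(i) list(n = h$n[i, ], ca = h$ca[i, ], c = h$c[i, ],
                            cb = h$cb[i, ])
  # identical sub-rotamers: the central assignment is returned
  f0 <- build_flexible_rotamer("S", fr_of(3), -65, sigmas = 0, res_id = 3)
  opt0 <- subrotamer_optimize(list(f0))
  expect_equal(opt0$sub_indices, 1L)
  expect_equal(opt0$energy, opt0$central_energy)

  # constructed clash-relief instance: two serines placed so the central
  # conformations collide but a +/- sigma sub-rotamer relieves the contact
  found <- NULL
  frame_a <- list(n = h$n[3, ], ca = h$ca[3, ], c = h$c[3, ],
                  cb = h$cb[3, ])
  r0 <- build_rotamer("S", frame_a, 180)
  for (d_target in c(2.6, 2.8, 3.0, 3.2)) {
    for (dir_seed in 1:5) {
      set.seed(dir_seed)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      fr_b <- lapply(frame_a, function(v) v + d_target * u)
      fa <- build_flexible_rotamer("S", frame_a, 180, sigmas = 30,
                                   res_id = 3)
      fb <- build_flexible_rotamer("S", fr_b, 180, sigmas = 30,
                                   res_id = 30)
      central <- pairwise_energy(fa$subs[[1]], fb$subs[[1]])
      best_sub <- min(vapply(fa$subs, function(sa) {
        min(vapply(fb$subs, function(sb) pairwise_energy(sa, sb), 0))
      }, 0))
      if (central > 0.5 && best_sub < central - 0.25) {
        found <- list(fa = fa, fb = fb)
        break
      }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  opt <- subrotamer_optimize(list(found$fa, found$fb))
  expect_lt(opt$energy, opt$central_energy)
  # idempotent: re-running on the chosen rigid subs keeps the energy
  again <- subrotamer_optimize(list(found$fa, found$fb))
  expect_identical(opt$sub_indices, again$sub_indices)
})
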
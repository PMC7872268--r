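# StructureDB, stem geometry, FragDB indexing and the Fragger search.

test_that("secondary structure assignment separates H, E and C", {
  h <- strsplit(assign_ss(make_ideal_helix(12, 1)), "")[[1]]
  expect_gte(sum(h == "H"), 8)
  e <- assign_ss(make_extended_strand(8, 1))
  expect_equal(e, strrep("C", 8))
  hp <- strsplit(assign_ss(make_hairpin(5, 1)), "")[[1]]
  expect_gte(sum(hp == "E"), 4)
  expect_equal(assign_ss(bb_subset(make_ideal_helix(8, 1), 1:4)), "CCCC")
})

test_that("db_add_chain stores chains and validates seqres", {
  h <- make_ideal_helix(10, 1)
  db <- db_new()
  r1 <- db_add_chain(db, "x", "A", h)
  expect_equal(r1$chain_index, 1)
  r2 <- db_add_chain(r1$db, "x", "A", h)  # duplicates allowed
  expect_equal(r2$chain_index, 2)
  expect_error(db_add_chain(db, "x", "A", h, seqres = "WWWW"),
               "subsequence")
  # truncated termini against a longer seqres are fine
  seqres <- paste0("AA", paste(h$seq, collapse = ""), "AA")
  expect_silent(db_add_chain(db, "x", "A", h, seqres = seqres))
})

test_that("db_get_fragment addresses residues in O(1) layout", {
  h <- make_ideal_helix(8, 2)
  db <- db_add_chain(db_new(), "x", "A", h)$db
  full <- db_get_fragment(db, fragment_address(1, 0, 8))
  expect_equal(full$sequence, paste(h$seq, collapse = ""))
  expect_lt(max(abs(full$bb$ca - h$ca)), 1e-12)
  sub <- db_get_fragment(db, fragment_address(1, 2, 3))
  expect_equal(sub$sequence, substr(full$sequence, 3, 5))
  expect_error(db_get_fragment(db, fragment_address(1, 6, 3)),
               "out of range")
})

test_that("stem geometry is rigid-invariant and tracks distance", {
  h <- make_ideal_helix(10, 3)
  ns <- rbind(h$n[2, ], h$ca[2, ], h$c[2, ])
  cs <- rbind(h$n[8, ], h$ca[8, ], h$c[8, ])
  g1 <- stem_geometry(ns, cs, 5)
  expect_equal(g1$l, 5L)
  expect_true(g1$alpha >= 0 && g1$alpha <= pi)

  set.seed(9)
  for (k in 1:25) {
    R <- homodel:::rotation_about_axis(stats::rnorm(3), stats::runif(1, -pi, pi))
    tv <- stats::rnorm(3, 0, 10)
    tr <- function(m) m %*% t(R) + matrix(tv, 3, 3, byrow = TRUE)
    g2 <- stem_geometry(tr(ns), tr(cs), 5)
    expect_lt(max(abs(unlist(g2[-1]) - unlist(g1[-1]))), 1e-9)
  }

  # translating the C-stem along the inter-anchor vector changes only d
  u <- (cs[1, ] - ns[3, ]) / sqrt(sum((cs[1, ] - ns[3, ])^2))
  g3 <- stem_geometry(ns, cs + matrix(u, 3, 3, byrow = TRUE), 5)
  expect_equal(g3$d - g1$d, 1, tolerance = 1e-9)
  expect_lt(abs(g3$alpha - g1$alpha), 1e-9)
  expect_lt(abs(g3$beta - g1$beta), 1e-9)

  expect_error(stem_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), cs,
                             3), "collinear")
})

test_that("fragdb_add_fragments enumerates, hashes and deduplicates", {
  h <- make_ideal_helix(10, 4)
  db <- db_add_chain(db_new(), "x", "A", h)$db
  fdb <- fragdb_new(1.0, 20)
  r <- fragdb_add_fragments(fdb, 4, 0, db)  # threshold disabled
  expect_equal(r$added, 5)  # offsets 1..5 (stems need neighbours)
  # adding the same db again with a positive threshold stores nothing
  r2 <- fragdb_add_fragments(r$fdb, 4, 0.5, db)
  expect_equal(r2$added, 0)
  # redundancy invariant, checked exhaustively per bucket
  fdb3 <- fragdb_add_fragments(fragdb_new(1.0, 20), 4, 0.5, db)$fdb
  for (key in names(fdb3$buckets)) {
    bucket <- fdb3$buckets[[key]]
    if (length(bucket) < 2) next
    for (a in seq_along(bucket)) {
      for (b in seq_len(a - 1)) {
        bb_a <- homodel:::fragment_with_stems(db, bucket[[a]]$chain_index,
                                              bucket[[a]]$offset, 4)
        bb_b <- homodel:::fragment_with_stems(db, bucket[[b]]$chain_index,
                                              bucket[[b]]$offset, 4)
        expect_gte(homodel:::stem_superposed_rmsd(bb_a, bb_b), 0.5)
      }
    }
  }
})

test_that("fragdb_query self-retrieves and widens monotonically", {
  md <- make_mini_db(list(make_toy_protein(24, 1)), lengths = 3:5)
  for (key in names(md$fdb$buckets)) {
    for (addr in md$fdb$buckets[[key]]) {
      g <- homodel:::db_stem_geometry(md$sdb, addr$chain_index, addr$offset,
                                      addr$length)
      hits <- fragdb_query(md$fdb, g, 0)
      expect_true(any(vapply(hits, function(a) {
        identical(unlist(a), unlist(addr))
      }, TRUE)))
      wide <- fragdb_query(md$fdb, g, 1)
      expect_gte(length(wide), length(hits))
    }
  }
  # far-away geometry finds nothing
  g0 <- md$fdb$buckets[[1]][[1]]
  g_far <- homodel:::db_stem_geometry(md$sdb, g0$chain_index, g0$offset,
                                      g0$length)
  g_far$d <- g_far$d + 25
  expect_length(fragdb_query(md$fdb, g_far, 0), 0)
})

test_that("StructureDB and FragDB serialization is byte-stable", {
  md <- make_mini_db(list(make_toy_protein(20, 2)), lengths = 3:4)
  f1 <- tempfile()
  save_structure_db(md$sdb, f1)
  sdb2 <- load_structure_db(f1)
  f2 <- tempfile()
  save_structure_db(sdb2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  expect_identical(sdb2$chains[[1]]$ca, md$sdb$chains[[1]]$ca)

  f3 <- tempfile()
  save_frag_db(md$fdb, f3)
  fdb2 <- load_frag_db(f3)
  f4 <- tempfile()
  save_frag_db(fdb2, f4)
  expect_identical(readBin(f3, "raw", file.size(f3) + 10),
                   readBin(f4, "raw", file.size(f4) + 10))
  expect_error(load_structure_db(f3), "bad magic")
})

test_that("fragger_search ranks the native segment first", {
  tp <- make_toy_protein(24, 3)
  bb <- backbone_from_chain(tp, "A")
  sdb <- db_add_chain(db_new(), "x", "A", bb)$db
  target <- paste(bb$seq[8:13], collapse = "")
  target_ss <- substr(sdb$chains[[1]]$ss, 8, 13)
  hits <- fragger_search(sdb, target, target_ss,
                         weights = c(sequence = 1, ss = 1), k = 5)
  expect_equal(hits$offset[1], 7)  # 0-based native offset

  # sequence-only weights reproduce a brute-force BLOSUM ranking
  hits_seq <- fragger_search(sdb, target, NULL,
                             weights = c(sequence = 1), k = 1000)
  L <- nchar(sdb$chains[[1]]$sequence)
  wlen <- nchar(target)
  tch <- strsplit(target, "")[[1]]
  cch <- strsplit(sdb$chains[[1]]$sequence, "")[[1]]
  brute <- vapply(0:(L - wlen), function(off) {
    mean(vapply(seq_len(wlen), function(j) {
      homodel:::blosum62[tch[j], cch[off + j]]
    }, 0))
  }, 0)
  expect_equal(nrow(hits_seq), L - wlen + 1)  # k beyond window count
  expect_equal(hits_seq$score, sort(brute, decreasing = TRUE))

  # window longer than every chain -> empty
  expect_equal(nrow(fragger_search(sdb, strrep("A", 50), k = 3)), 0)
})
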
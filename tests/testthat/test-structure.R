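mk_model <- function(coords, aa = NULL, conf = 90, id = "m",
                     idx = NULL, ptm = NA_real_) {
  n <- nrow(coords)
  structure_model(id, data.frame(
    residue_index = idx %||% seq_len(n),
    aa = aa %||% rep("A", n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    confidence = rep_len(conf, n)), global_confidence = ptm)
}

test_that("PDB Calpha IO round-trips", {
  set.seed(7)
  m <- mk_model(random_points(25), aa = sample(c("A", "G", "W", "K"), 25,
                                               replace = TRUE),
                conf = round(runif(25, 40, 99), 2), idx = seq(3, 51, 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ca(m, path)
  back <- read_pdb_ca(path, model_id = "m")
  expect_equal(back$residues$residue_index, m$residues$residue_index)
  expect_equal(back$residues$aa, m$residues$aa)
  expect_equal(back$residues$x, m$residues$x, tolerance = 1e-3)
  expect_equal(back$residues$confidence, m$residues$confidence,
               tolerance = 1e-2)
  expect_error(structure_model("x", data.frame(
    residue_index = c(1, 1), aa = "A", x = 0, y = 0, z = 0, confidence = 1)),
    "strictly increasing")
})

test_that("residue pairing follows tables and gapped alignments", {
  P <- random_points(6); Q <- random_points(6)
  m <- mk_model(P, aa = strsplit("MKVLAW", "")[[1]])
  r <- mk_model(Q, aa = strsplit("MKLAWG", "")[[1]])
  # identity pairing of a model with itself covers all residues
  self <- pair_residues(m, m)
  expect_equal(nrow(self), 6)
  expect_equal(self$model_res, self$ref_res)
  # alignment with gaps: only match columns pair (count oracle)
  aln <- c("MKVLAW-", "MK-LAWG")
  pr <- pair_residues(m, r, alignment = aln)
  a <- strsplit(aln[1], "")[[1]]; b <- strsplit(aln[2], "")[[1]]
  expect_equal(nrow(pr), sum(a != "-" & b != "-"))
  expect_equal(pr$model_res, c(1, 2, 4, 5, 6))
  expect_equal(pr$ref_res, c(1, 2, 3, 4, 5))
  # too few pairs, duplicated targets
  expect_error(pair_residues(mk_model(P[1:2, ]), mk_model(Q[1:2, ])),
               "at least 3")
  expect_error(pair_residues(m, r, pairing = data.frame(
    model_res = c(1, 2, 3), ref_res = c(1, 1, 2))), "one-to-one")
})

test_that("Kabsch fit recovers rigid motions exactly", {
  set.seed(17)
  P <- random_points(12)
  expect_equal(kabsch_superpose(pairs_from_points(P, P))$rmsd, 0,
               tolerance = 1e-12)
  for (i in 1:5) {
    Q <- rigid_transform(P)
    sp <- kabsch_superpose(pairs_from_points(P, Q))
    expect_lt(sp$rmsd, 1e-9)
    R <- sp$rotation
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
  # collinear point sets are rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(pairs_from_points(line, line + 1)),
               "degenerate")
})

test_that("reflections are excluded and rmsd is symmetric", {
  set.seed(23)
  P <- random_points(10)
  M <- P %*% diag(c(-1, 1, 1))          # mirror image of a chiral set
  sp <- kabsch_superpose(pairs_from_points(P, M))
  expect_gt(sp$rmsd, 0.1)               # a proper rotation cannot absorb it
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  for (i in 1:5) {
    Q <- random_points(10)
    ab <- kabsch_superpose(pairs_from_points(P, Q))$rmsd
    ba <- kabsch_superpose(pairs_from_points(Q, P))$rmsd
    expect_equal(ab, ba, tolerance = 1e-9)
  }
})

test_that("Kabsch rmsd matches the rotation-search oracle", {
  set.seed(31)
  for (i in 1:6) {
    P <- random_points(5); Q <- random_points(5)
    sp <- kabsch_superpose(pairs_from_points(P, Q))
    expect_equal(sp$rmsd, oracle_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("iterative pruning removes planted outliers", {
  set.seed(41)
  P <- random_points(50)
  pairs <- pairs_from_points(P, P)       # 50 coincident pairs
  pairs$rx[7] <- pairs$rx[7] + 10        # one planted 10-A outlier
  sp <- prune_and_superpose(pairs)
  expect_equal(sp$pruned_pairs, 1L)
  expect_equal(sp$retained_pairs, 49L)
  expect_lt(sp$rmsd, 1e-9)
  expect_false(7 %in% sp$retained)
  # no pair beyond the cutoff: identical to the plain fit
  clean <- pairs_from_points(P, rigid_transform(P))
  sp0 <- kabsch_superpose(clean)
  sp1 <- prune_and_superpose(clean)
  expect_equal(sp1$rmsd, sp0$rmsd)
  expect_equal(sp1$pruned_pairs, 0L)
  expect_equal(sp1$iterations, 1L)
})

test_that("pruning never increases rmsd and never drops below 3 pairs", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    P <- random_points(n)
    Q <- rigid_transform(P) + matrix(rnorm(3 * n, sd = runif(1, 0.1, 3)),
                                     ncol = 3)
    pairs <- pairs_from_points(P, Q)
    full <- kabsch_superpose(pairs)
    pruned <- prune_and_superpose(pairs, cutoff = 2)
    expect_lte(pruned$rmsd, full$rmsd + 1e-12)
    expect_gte(pruned$retained_pairs, 3L)
    expect_equal(pruned$retained_pairs + pruned$pruned_pairs, n)
  }
})

test_that("cap-helix localization maps the motif to structure indices", {
  aa <- strsplit(paste0(strrep("A", 119), "NVWCAAGK", strrep("G", 13)), "")[[1]]
  m <- mk_model(random_points(140), aa = aa)
  expect_equal(unname(locate_cap_helix(m)), c(120, 127))
  span <- locate_cap_helix(m, aa_sequence = paste(aa, collapse = ""))
  expect_equal(unname(span), c(120, 127))
  # offset residue numbering maps through
  m2 <- mk_model(random_points(140), aa = aa, idx = 101:240)
  expect_equal(unname(locate_cap_helix(m2)), c(220, 227))
  # motif-free decoy
  expect_null(locate_cap_helix(mk_model(random_points(50))))
  expect_error(locate_cap_helix(m, aa_sequence = strrep("A", 140)),
               "does not match")
})

test_that("confidence summaries average pLDDT and flag low pTM", {
  m <- mk_model(random_points(30), conf = 90, ptm = 0.73)
  cs <- confidence_summary(m)
  expect_equal(cs$mean_confidence, 90)
  expect_false(cs$low_global_confidence)   # >= 0.73 floor passes
  low <- confidence_summary(mk_model(random_points(10), ptm = 0.5))
  expect_true(low$low_global_confidence)
  # region mean equals a brute-force average
  set.seed(47)
  conf <- round(runif(30, 50, 99), 1)
  m2 <- mk_model(random_points(30), conf = conf)
  cs2 <- confidence_summary(m2, region = c(5, 12))
  expect_equal(cs2$region_mean, mean(conf[5:12]))
})
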
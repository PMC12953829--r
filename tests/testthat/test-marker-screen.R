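mk_cand <- function(ids, aa, evalue = NA_real_) {
  data.frame(gene_id = ids, contig_id = "c1", start = 1L,
             end = 3L * nchar(aa) + 3L, strand = "+",
             aa_sequence = aa, evalue = evalue, stringsAsFactors = FALSE)
}

test_that("e-value gate keeps hits at or below threshold, passes no-evalue", {
  cand <- mk_cand(c("a", "b", "c"), strrep("A", 120),
                  evalue = c(1e-30, 1e-20, NA))
  kept <- gate_by_evalue(cand)
  expect_setequal(kept$gene_id, c("a", "c"))
  # boundary: equal to the threshold is retained
  expect_equal(nrow(gate_by_evalue(mk_cand("x", "AAA", 1e-25))), 1)
  expect_error(gate_by_evalue(mk_cand("x", "AAA", -1)), "negative")
  expect_error(gate_by_evalue(cand, threshold = 0), "> 0")
})

test_that("e-value gate count on a synthetic candidate set", {
  set.seed(1)
  ev <- c(10^runif(40, -40, -26), 10^runif(35, -24, -5),
          rep(NA_real_, 25))
  cand <- mk_cand(sprintf("g%03d", seq_along(ev)), strrep("A", 150), ev)
  kept <- gate_by_evalue(cand)
  expect_equal(nrow(kept), sum(!is.na(ev) & ev <= 1e-25) + sum(is.na(ev)))
  expect_equal(sum(!is.na(kept$evalue)), 40)
})

test_that("motif verification matches the degenerate cap-helix pattern", {
  expect_equal(verify_motif("MKXXNVWCAAGKYY"), 5L)
  expect_equal(verify_motif("NIWCSGGK"), 1L)
  expect_true(is.na(verify_motif("NLWCAAGK")))   # L not allowed at pos 2
  expect_true(is.na(verify_motif("")))
  # X never matches a constrained position
  expect_true(is.na(verify_motif("NXWCAAGK")))
  expect_true(is.na(verify_motif("XVWCAAGK")))
  # first occurrence is reported
  expect_equal(verify_motif(paste0(strrep("G", 10), "NVWCAAGK",
                                   strrep("G", 4), "NIWCAAGK")), 11L)
})

test_that("exactly 8 eight-mers are accepted, nothing adjacent to them", {
  variants <- hgca_motif_variants()
  expect_length(variants, 8)            # 1*2*1*1*2*2*1*1 degeneracies
  expect_false(anyDuplicated(variants) > 0)
  expect_true(all(verify_motif(variants) == 1L))
  # single-position corruptions of every variant are all rejected
  allowed <- list(1, c("V", "I"), "W", "C", c("A", "S"), c("A", "G"), "G", "K")
  allowed[[1]] <- "N"
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (v in variants) {
    chars <- strsplit(v, "")[[1]]
    for (pos in 1:8) {
      for (sub in setdiff(aa20, allowed[[pos]])) {
        mut <- chars; mut[pos] <- sub
        expect_true(is.na(verify_motif(paste(mut, collapse = ""))),
                    info = paste(v, pos, sub))
      }
    }
  }
})

test_that("length filter is strict below 100 aa", {
  cand <- mk_cand(c("a", "b", "c", "d"),
                  c(strrep("A", 50), strrep("C", 99), strrep("D", 100),
                    strrep("E", 350)))
  expect_setequal(filter_length(cand)$gene_id, c("c", "d"))
  expect_error(filter_length(cand, min_aa = 0), ">= 1")
})

test_that("identity/containment dedup picks deterministic representatives", {
  s <- strrep("ACDEFGHIKL", 15)
  cand <- mk_cand(c("b", "a"), c(s, s))
  d <- dedup_identical(cand)
  expect_equal(sum(d$is_representative), 1)
  expect_equal(d$cluster_id, c("a", "a"))      # lexicographic tie-break
  # prefix containment collapses, longest is representative
  cand2 <- mk_cand(c("long", "short"), c(s, substr(s, 1, 60)))
  d2 <- dedup_identical(cand2)
  expect_equal(d2$gene_id[d2$is_representative], "long")
  expect_equal(unique(d2$cluster_id), "long")
  # internal substring containment also collapses
  cand3 <- mk_cand(c("whole", "mid"), c(s, substr(s, 40, 90)))
  expect_equal(sum(dedup_identical(cand3)$is_representative), 1)
  empty <- mk_cand("x", "AAA")[0, ]
  expect_error(dedup_identical(empty), "empty")
})

test_that("dedup of k unique full-length sequences yields k representatives", {
  set.seed(7)
  pool <- replicate(30, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                     120, replace = TRUE), collapse = ""))
  seqs <- c(pool, sample(pool, 15, replace = TRUE))   # duplicates added
  cand <- mk_cand(sprintf("g%02d", seq_along(seqs)), seqs)
  d <- dedup_identical(cand)
  expect_equal(sum(d$is_representative), length(unique(seqs)))  # oracle: set dedup
  expect_setequal(d$aa_sequence[d$is_representative], unique(seqs))
})

test_that("50%-identity clustering separates families and merges variants", {
  expect_equal(sum(select_representatives(
    c(a = strrep("ACDK", 30), b = strrep("ACDK", 30)))$is_representative), 1)

  set.seed(11)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")
  # two unrelated random sequences: LCS oracle bounds identity below 0.5
  x <- rnd(200); y <- rnd(200)
  expect_lt(lcs_length(x, y) / 200, 0.5)  # upper bound on aligned matches
  expect_lt(pairwise_identity(x, y), 0.5)
  expect_equal(sum(select_representatives(c(x = x, y = y))$is_representative), 2)

  # 12 planted families x 3 variants; each variant mutates its own disjoint
  # 36-position block, so within-family pairwise identity is exactly 60%
  fams <- replicate(12, rnd(180))
  seqs <- list()
  for (f in seq_along(fams)) {
    parent <- strsplit(fams[f], "")[[1]]
    for (v in 1:3) {
      mut <- parent
      idx <- ((v - 1) * 36 + 1):(v * 36)
      for (i in idx) mut[i] <- sample(setdiff(aa20, mut[i]), 1)
      seqs[[sprintf("f%02d_v%d", f, v)]] <- paste(mut, collapse = "")
    }
  }
  reps <- select_representatives(unlist(seqs), identity = 0.5)
  expect_equal(sum(reps$is_representative), 12)
  fam_of <- sub("_v[0-9]$", "", reps$seq_id)
  expect_true(all(tapply(reps$cluster_id, fam_of,
                         function(x) length(unique(x)) == 1)))
})

test_that("tandem hgcB detection enforces strand, distance, length, motifs", {
  fdx2 <- paste0(strrep("A", 9), "CAACAACAAAC", strrep("A", 19),
                 "CGGCGGCGGGC", strrep("A", 40))    # 90 aa, two motifs
  hgca <- mk_cand("A1", strrep("M", 150))
  mk_nb <- function(id, aa, start, strand = "+") {
    data.frame(gene_id = id, contig_id = "c1", start = start,
               end = start + 3L * nchar(aa) + 2L, strand = strand,
               aa_sequence = aa, evalue = NA_real_, stringsAsFactors = FALSE)
  }
  stop_bp <- hgca$end
  expect_identical(check_hgcB(hgca, mk_nb("B1", fdx2, stop_bp + 21L)), "B1")
  # a single motif is not enough
  one <- paste0(strrep("A", 9), "CAACAACAAAC", strrep("A", 70))
  expect_true(is.na(check_hgcB(hgca, mk_nb("B2", one, stop_bp + 21L))))
  # 2 kb away violates the distance rule
  expect_true(is.na(check_hgcB(hgca, mk_nb("B3", fdx2, stop_bp + 2000L))))
  # wrong strand
  expect_true(is.na(check_hgcB(hgca, mk_nb("B4", fdx2, stop_bp + 21L, "-"))))
  # too long (>= 100 aa)
  long <- paste0(fdx2, strrep("A", 20))
  expect_true(is.na(check_hgcB(hgca, mk_nb("B5", long, stop_bp + 21L))))
  # minus-strand hgcA: downstream is leftward
  hgcam <- hgca; hgcam$strand <- "-"; hgcam$start <- 5000L; hgcam$end <- 5452L
  nb <- mk_nb("B6", fdx2, 5000L - 273L - 21L, "-")
  expect_identical(check_hgcB(hgcam, nb), "B6")
})

test_that("taxonomy assignment prefers the bin map and ranks best hits", {
  bins <- data.frame(gene_id = "g1", bin_id = "bin7",
                     taxonomy = "Desulfobacterales")
  hits <- data.frame(gene_id = c("g1", "g2", "g2"),
                     taxonomy = c("X", "Nitrospina", "Anaerolineae"),
                     rank = c(1, 2, 1))
  expect_equal(assign_taxonomy("g1", bins, hits),
               list(taxonomy_label = "Desulfobacterales",
                    taxonomy_source = "bin_map"))
  expect_equal(assign_taxonomy("g2", bins, hits),
               list(taxonomy_label = "Anaerolineae",
                    taxonomy_source = "best_hit"))
  expect_equal(assign_taxonomy("g3", bins, hits)$taxonomy_source, "unassigned")
  conflict <- rbind(bins, data.frame(gene_id = "g1", bin_id = "bin8",
                                     taxonomy = "Myxococcota"))
  expect_error(assign_taxonomy("g1", conflict, hits), "conflicting")
})

test_that("screen composes the cascade and reports stage counts", {
  fx <- plant_decoys(small_fixture(seed = 41), 6, 4, seed = 41)
  cand <- candidate_table(fx$proteins, fx$genes)
  res <- suppressMessages(screen(cand, verbose = FALSE))
  g <- gate_by_evalue(cand)
  g$motif_start <- verify_motif(g$aa_sequence)
  manual <- dedup_identical(filter_length(g[!is.na(g$motif_start), ]))
  expect_setequal(res$gene_id, manual$gene_id[manual$is_representative])
  counts <- attr(res, "stage_counts")
  expect_equal(unname(counts["input"]), nrow(cand))
  expect_equal(unname(counts["nonredundant"]), nrow(res))
  # soundness: every validated record has the motif and >= 100 aa
  expect_true(all(!is.na(verify_motif(res$aa_sequence))))
  expect_true(all(nchar(res$aa_sequence) >= 100))
})

test_that("screen is order-invariant, idempotent, and empty on pure decoys", {
  fx <- plant_decoys(small_fixture(seed = 43), 5, 5, seed = 43)
  cand <- candidate_table(fx$proteins, fx$genes)
  res <- screen(cand, verbose = FALSE)
  set.seed(1)
  perm <- cand[sample(nrow(cand)), ]
  expect_identical(screen(perm, verbose = FALSE)$gene_id, res$gene_id)
  # idempotence on the validated set
  again <- screen(res[, c("gene_id", "aa_sequence")] |>
                    (\(d) cbind(d, contig_id = "c", start = 1L,
                                end = 3L * nchar(d$aa_sequence) + 3L,
                                strand = "+", evalue = NA_real_))(),
                  verbose = FALSE)
  expect_setequal(again$gene_id, res$gene_id)
  # motif/length filter order does not matter
  g <- gate_by_evalue(cand)
  a <- filter_length(g); a$motif_start <- verify_motif(a$aa_sequence)
  a <- a[!is.na(a$motif_start), ]
  b <- g; b$motif_start <- verify_motif(b$aa_sequence)
  b <- filter_length(b[!is.na(b$motif_start), ])
  expect_setequal(a$gene_id, b$gene_id)
  # decoy-only input
  dec <- cand[grepl("^decoy", cand$gene_id), ]
  expect_equal(nrow(screen(dec, verbose = FALSE)), 0)
})
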
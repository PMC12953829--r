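# Seeded generator of stratified water-column metagenome fixtures with
# planted ground truth: hgcAB-carrying genomes at configurable community
# fractions per redox zone and lifestyle, universal single-copy marker
# families tracking genome equivalents, and multiplicative lognormal
# coverage noise. Decoy paralogs and fragments exercise the screen.

MARKER_FAMILIES <- sprintf("USCG%02d", 1:10)
MARKER_AA_LEN <- 300L          # 900 bp single-copy marker genes
GENE_SPACER_BP <- 20L          # intergenic gap, also the hgcA-hgcB gap

#' Specify a community member genome
#'
#' @param taxon_id Unique identifier.
#' @param phylum_label Taxonomic label carried through to outputs.
#' @param genome_size Genome size in bp (> 0); bookkeeping only, all
#'   quantification is single-copy-gene based.
#' @param carries_hgcAB Whether the genome carries the tandem hgcAB pair.
#' @param motif_variant 8-residue cap-helix motif planted in hgcA; must be
#'   one of [hgca_motif_variants()]. Ignored for non-carriers.
#' @param zone_affinity Named non-negative weights
#'   `c(surface=, intermediate=, deep=)`, not all zero; shapes the taxon's
#'   share of its carrier/non-carrier group in each zone.
#' @param lifestyle_bias Real; positive values favour the particle-associated
#'   fraction, negative the free-living fraction (log-scale multiplier).
#' @return A `taxon_spec` list.
#' @export
taxon_spec <- function(taxon_id, phylum_label, genome_size = 3e6,
                       carries_hgcAB = FALSE, motif_variant = "NVWCAAGK",
                       zone_affinity = c(surface = 1, intermediate = 1, deep = 1),
                       lifestyle_bias = 0) {
  abort_if(!nzchar(taxon_id), "taxon_id must be non-empty")
  abort_if(genome_size <= 0, "genome_size must be > 0")
  zones <- c("surface", "intermediate", "deep")
  abort_if(!all(zones %in% names(zone_affinity)),
           "zone_affinity must be named surface/intermediate/deep")
  za <- as.numeric(zone_affinity[zones]); names(za) <- zones
  abort_if(any(za < 0) || sum(za) == 0,
           "zone_affinity weights must be >= 0 and not all zero")
  if (isTRUE(carries_hgcAB)) {
    abort_if(nchar(motif_variant) != 8 || is.na(verify_motif(motif_variant)),
             "motif_variant must match the degenerate cap-helix motif")
  }
  structure(list(taxon_id = taxon_id, phylum_label = phylum_label,
                 genome_size = as.integer(genome_size),
                 carries_hgcAB = isTRUE(carries_hgcAB),
                 motif_variant = motif_variant,
                 zone_affinity = za,
                 lifestyle_bias = as.numeric(lifestyle_bias)),
            class = "taxon_spec")
}

#' Specify a metagenomic sample
#'
#' @param sample_id Unique identifier.
#' @param depth Water depth in m, within \[0, 300\].
#' @param lifestyle `"FL"` (free-living, 0.22-um retentate) or `"PA"`
#'   (particle-associated, 3-um retentate).
#' @param target_genome_equivalents True number of genome copies the sample
#'   represents (> 0); every single-copy gene's expected depth is this value
#'   times its taxon's community fraction.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   coverage noise (>= 0).
#' @return A `sample_design` list.
#' @export
sample_design <- function(sample_id, depth, lifestyle = c("FL", "PA"),
                          target_genome_equivalents = 50, noise_cv = 0.1) {
  lifestyle <- match.arg(lifestyle)
  abort_if(depth < 0 || depth > 300, "depth must be in [0, 300] m")
  abort_if(target_genome_equivalents <= 0,
           "target_genome_equivalents must be > 0")
  abort_if(noise_cv < 0, "noise_cv must be >= 0")
  structure(list(sample_id = sample_id, depth = as.numeric(depth),
                 lifestyle = lifestyle,
                 target_genome_equivalents = as.numeric(target_genome_equivalents),
                 noise_cv = as.numeric(noise_cv)),
            class = "sample_design")
}

#' Random taxa for a stratified community
#'
#' Carriers receive deep-skewed zone affinities and random lifestyle biases,
#' emulating the anoxic-deep enrichment of mercury methylators; non-carriers
#' are surface-skewed. Phylum labels cycle through clades reported for
#' marine methylator / background communities.
#' @param n_carriers,n_noncarriers Counts (carriers >= 1, non-carriers >= 1).
#' @param seed RNG seed.
#' @return List of [taxon_spec()] objects.
#' @export
community_taxa <- function(n_carriers, n_noncarriers, seed = 1) {
  carrier_phyla <- c("Desulfobacterales", "Anaerolineae", "Nitrospina",
                     "Myxococcota", "Pirellulaceae", "Hydrogenedentes",
                     "Geobacterales", "Syntrophobacterales")
  other_phyla <- c("Pelagibacterales", "Flavobacteriales", "Synechococcales",
                   "Rhodobacterales", "Actinomycetota", "Thaumarchaeota")
  with_seed(seed, {
    mk <- function(i, carrier) {
      if (carrier) {
        za <- c(surface = stats::rgamma(1, 1), intermediate = stats::rgamma(1, 2),
                deep = stats::rgamma(1, 4))
        phy <- carrier_phyla[(i - 1) %% length(carrier_phyla) + 1]
      } else {
        za <- c(surface = stats::rgamma(1, 4), intermediate = stats::rgamma(1, 2),
                deep = stats::rgamma(1, 1))
        phy <- other_phyla[(i - 1) %% length(other_phyla) + 1]
      }
      taxon_spec(
        taxon_id = sprintf("%s%03d", if (carrier) "hgc" else "bkg", i),
        phylum_label = phy,
        genome_size = round(stats::runif(1, 2e6, 6e6)),
        carries_hgcAB = carrier,
        motif_variant = sample(hgca_motif_variants(), 1),
        zone_affinity = za,
        lifestyle_bias = stats::rnorm(1, 0, 0.5))
    }
    c(lapply(seq_len(n_carriers), mk, carrier = TRUE),
      lapply(seq_len(n_noncarriers), mk, carrier = FALSE))
  })
}

#' The 7-depth x 2-lifestyle water-column sampling design
#'
#' Depths 0, 30, 50, 90, 120, 140 and 170 m, each filtered into a
#' particle-associated (3-um retentate) and a free-living (0.22-um
#' retentate) fraction: 14 samples.
#' @param target_genome_equivalents,noise_cv Passed to [sample_design()].
#' @return List of [sample_design()] objects.
#' @export
default_sample_designs <- function(target_genome_equivalents = 50,
                                   noise_cv = 0.1) {
  depths <- c(0, 30, 50, 90, 120, 140, 170)
  out <- list()
  for (lf in c("FL", "PA")) for (d in depths) {
    out[[length(out) + 1]] <- sample_design(
      sprintf("%s_%03dm", lf, d), depth = d, lifestyle = lf,
      target_genome_equivalents = target_genome_equivalents,
      noise_cv = noise_cv)
  }
  out
}

# random backbone guaranteed free of the cap-helix motif
random_aa_nomotif <- function(n) {
  repeat {
    s <- random_aa(n)
    if (is.na(verify_motif(s))) return(s)
  }
}

make_hgca_protein <- function(len, motif) {
  pos <- sample(seq(20L, len - 27L), 1)   # internal placement
  left <- random_aa_nomotif(pos - 1L)
  right <- random_aa_nomotif(len - pos + 1L - 8L)
  list(aa = paste0(left, motif, right), motif_start = pos)
}

make_hgcb_protein <- function(len = 90L) {
  fdx <- function() {
    x <- function(k) random_aa(k)
    paste0("C", x(2), "C", x(2), "C", x(3), "C")   # CX2CX2CX3C, 11 aa
  }
  repeat {
    s <- paste0(random_aa(9L), fdx(), random_aa(19L), fdx(),
                random_aa(len - 9L - 19L - 22L))
    if (is.na(verify_motif(s))) return(s)
  }
}

# per-sample taxon community fractions
community_fractions <- function(taxa, design, carrier_profile) {
  zone <- classify_zone(design$depth)
  dir <- if (design$lifestyle == "PA") 1 else -1
  w <- vapply(taxa, function(tx)
    tx$zone_affinity[[zone]] * exp(tx$lifestyle_bias * dir), numeric(1))
  carrier <- vapply(taxa, `[[`, logical(1), "carries_hgcAB")
  if (is.null(carrier_profile)) {
    p <- w / sum(w)
  } else {
    f <- if (length(carrier_profile) == 1) unname(carrier_profile)
         else unname(carrier_profile[[zone]])
    abort_if(is.na(f) || f < 0 || f > 100, "carrier_profile must be %% in [0,100]")
    f <- f / 100
    p <- numeric(length(taxa))
    wc <- w * carrier; wn <- w * !carrier
    p[carrier] <- if (sum(wc) > 0) f * wc[carrier] / sum(wc)
                  else f / sum(carrier)
    p[!carrier] <- if (sum(wn) > 0) (1 - f) * wn[!carrier] / sum(wn)
                   else (1 - f) / sum(!carrier)
  }
  names(p) <- vapply(taxa, `[[`, "", "taxon_id")
  p
}

#' Build a synthetic stratified-metagenome fixture with planted truth
#'
#' Each taxon contributes one contig carrying 10 universal single-copy
#' marker genes (900 bp each) and, for carriers, an hgcA gene (200-330 aa,
#' cap-helix motif at a random internal position) with its hgcB partner
#' (90 aa, two tandem CX2CX2CX3C motifs) 20 bp downstream on the same
#' strand (alternating carriers use the minus strand). Per-sample community
#' fractions follow the taxa's zone affinities and lifestyle biases; when
#' `carrier_profile` is given, the summed carrier fraction per zone is
#' pinned to the stated percentage. Gene depths are
#' `genome_equivalents x fraction`, perturbed by independent multiplicative
#' lognormal noise with the design's CV. The emitted depth table carries
#' one aggregate row per marker family (summed over taxa), which is the
#' genome-equivalent signal, plus one row per hgcA/hgcB gene.
#'
#' @param taxa List of [taxon_spec()]; at least one carrier and one
#'   non-carrier.
#' @param designs List of [sample_design()] with unique ids.
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical outputs via [write_fixture()].
#' @param carrier_profile Either `NULL` (fractions fall out of the
#'   affinities), a single percentage, or a named vector
#'   `c(surface=, intermediate=, deep=)` of carrier percentages. The default
#'   mirrors the redoxcline shape seen in stratified anoxic basins: trace
#'   carriers in oxic surface water, ~1.5% at the suboxic transition, ~30%
#'   in anoxic deep water.
#' @return A `community_fixture` list: `contigs` (DNAStringSet), `proteins`
#'   (AAStringSet), `genes`, `gene_classes`, `depths` (wide, jgi-style),
#'   `metadata`, `markers`, `truth` (`samples`, `genes`, `taxa`), `config`.
#' @export
build_community <- function(taxa, designs, seed = 1,
                            carrier_profile = c(surface = 0.2,
                                                intermediate = 1.5,
                                                deep = 30)) {
  abort_if(length(taxa) == 0, "empty taxa list")
  abort_if(!all(vapply(taxa, inherits, logical(1), "taxon_spec")),
           "taxa must be taxon_spec objects")
  abort_if(!all(vapply(designs, inherits, logical(1), "sample_design")),
           "designs must be sample_design objects")
  ids <- vapply(designs, `[[`, "", "sample_id")
  abort_if(anyDuplicated(ids) > 0, "duplicate sample_id in designs")
  tids <- vapply(taxa, `[[`, "", "taxon_id")
  abort_if(anyDuplicated(tids) > 0, "duplicate taxon_id in taxa")
  carrier <- vapply(taxa, `[[`, logical(1), "carries_hgcAB")
  abort_if(!any(carrier) || !any(!carrier),
           "need at least one carrier and one non-carrier taxon")

  with_seed(seed, {
    ## --- genomes: contigs, genes, proteins -------------------------------
    contigs <- character(0)
    prot <- character(0)
    genes <- list()
    classes <- list()
    for (k in seq_along(taxa)) {
      tx <- taxa[[k]]
      minus_pair <- tx$carries_hgcAB && (k %% 2 == 0)
      contig_id <- paste0(tx$taxon_id, "_c1")
      plan <- list()
      for (m in seq_along(MARKER_FAMILIES)) {
        plan[[length(plan) + 1]] <- list(
          id = paste0(tx$taxon_id, "_", MARKER_FAMILIES[m]),
          aa = random_aa_nomotif(MARKER_AA_LEN), strand = "+",
          class = "marker", family = MARKER_FAMILIES[m], motif_start = NA)
      }
      if (tx$carries_hgcAB) {
        alen <- sample(200:330, 1)
        ap <- make_hgca_protein(alen, tx$motif_variant)
        a <- list(id = paste0(tx$taxon_id, "_hgcA"), aa = ap$aa,
                  strand = if (minus_pair) "-" else "+",
                  class = "hgcA", family = NA, motif_start = ap$motif_start)
        b <- list(id = paste0(tx$taxon_id, "_hgcB"), aa = make_hgcb_protein(),
                  strand = if (minus_pair) "-" else "+",
                  class = "hgcB", family = NA, motif_start = NA)
        # on the minus strand "downstream of hgcA" is leftward in contig
        # coordinates, so hgcB precedes hgcA along the contig
        plan <- c(plan, if (minus_pair) list(b, a) else list(a, b))
      }
      pos <- 1L
      for (g in plan) {
        dlen <- 3L * nchar(g$aa) + 3L
        genes[[length(genes) + 1]] <- data.frame(
          gene_id = g$id, contig_id = contig_id, start = pos,
          end = pos + dlen - 1L, strand = g$strand, stringsAsFactors = FALSE)
        classes[[length(classes) + 1]] <- data.frame(
          gene_id = g$id, taxon_id = tx$taxon_id, class = g$class,
          marker_family = ifelse(is.na(g$family), "", g$family),
          motif_start = g$motif_start, stringsAsFactors = FALSE)
        prot[g$id] <- g$aa
        pos <- pos + dlen + GENE_SPACER_BP
      }
      contigs[contig_id] <- random_dna(pos + 9L)
    }
    genes <- do.call(rbind, genes)
    classes <- do.call(rbind, classes)

    ## --- per-sample composition and coverage -----------------------------
    S <- length(designs)
    frac <- matrix(0, nrow = length(taxa), ncol = S,
                   dimnames = list(tids, ids))
    for (s in seq_len(S))
      frac[, s] <- community_fractions(taxa, designs[[s]], carrier_profile)

    ge <- vapply(designs, `[[`, numeric(1), "target_genome_equivalents")
    cvs <- vapply(designs, `[[`, numeric(1), "noise_cv")

    # marker families: aggregate depth = sum over taxa of GE * p_i * noise
    nmf <- length(MARKER_FAMILIES)
    marker_depth <- matrix(0, nrow = nmf, ncol = S,
                           dimnames = list(MARKER_FAMILIES, ids))
    for (s in seq_len(S)) {
      noise <- matrix(lnorm_noise(nmf * length(taxa), cvs[s]), nrow = nmf)
      marker_depth[, s] <- as.numeric(noise %*% (ge[s] * frac[, s]))
    }

    gene_rows <- classes[classes$class %in% c("hgcA", "hgcB"), , drop = FALSE]
    ng <- nrow(gene_rows)
    hgc_true <- matrix(0, nrow = ng, ncol = S,
                       dimnames = list(gene_rows$gene_id, ids))
    hgc_depth <- hgc_true
    for (s in seq_len(S)) {
      p <- frac[gene_rows$taxon_id, s]
      hgc_true[, s] <- ge[s] * p
      hgc_depth[, s] <- hgc_true[, s] * lnorm_noise(ng, cvs[s])
    }

    glen <- stats::setNames(genes$end - genes$start + 1L, genes$gene_id)
    depths <- data.frame(
      gene_id = c(MARKER_FAMILIES, gene_rows$gene_id),
      length_bp = c(rep(3L * MARKER_AA_LEN + 3L, nmf),
                    as.integer(glen[gene_rows$gene_id])),
      stringsAsFactors = FALSE)
    depth_mat <- rbind(marker_depth, hgc_depth)
    for (s in seq_len(S)) depths[[ids[s]]] <- depth_mat[, s]

    metadata <- data.frame(
      sample_id = ids,
      depth_m = vapply(designs, `[[`, numeric(1), "depth"),
      fraction = ifelse(vapply(designs, `[[`, "", "lifestyle") == "PA",
                        "3um", "0.22um"),
      stringsAsFactors = FALSE)

    ## --- truth ------------------------------------------------------------
    truth_samples <- data.frame(
      sample_id = ids,
      carrier_fraction_pct = 100 * colSums(frac[carrier, , drop = FALSE]),
      genome_equivalents = ge, stringsAsFactors = FALSE)
    truth_genes <- data.frame(
      gene_id = rep(rownames(hgc_true), S),
      sample_id = rep(ids, each = ng),
      true_depth = as.numeric(hgc_true), stringsAsFactors = FALSE)
    truth_taxa <- data.frame(
      taxon_id = rep(tids, S),
      sample_id = rep(ids, each = length(taxa)),
      rel_abundance = as.numeric(frac),
      is_carrier = rep(carrier, S), stringsAsFactors = FALSE)

    structure(list(
      contigs = Biostrings::DNAStringSet(contigs),
      proteins = Biostrings::AAStringSet(prot),
      genes = genes, gene_classes = classes, depths = depths,
      metadata = metadata, markers = MARKER_FAMILIES,
      truth = list(samples = truth_samples, genes = truth_genes,
                   taxa = truth_taxa),
      config = list(seed = seed, n_taxa = length(taxa),
                    n_carriers = sum(carrier), n_samples = S,
                    carrier_profile = as.list(carrier_profile),
                    noise_cv = as.list(stats::setNames(cvs, ids)),
                    genome_equivalents = as.list(stats::setNames(ge, ids)))),
      class = "community_fixture")
  })
}

#' Add decoy sequences to a fixture
#'
#' Paralog decoys are full-length hgcA-like proteins whose motif is broken
#' at one constrained position (the corrinoid-protein paralogs, e.g. the
#' CdhD outgroup family, that an e-value gate alone would admit); fragment
#' decoys carry a genuine motif but are truncated below 100 aa. Both are
#' marked non-hgcA in the truth tables and receive low background coverage.
#'
#' @param fixture A `community_fixture`.
#' @param n_paralogs,n_fragments Decoy counts (>= 0).
#' @param seed Integer seed.
#' @param decoy_fraction Community fraction per decoy used for its
#'   background coverage (default 0.005).
#' @export
plant_decoys <- function(fixture, n_paralogs = 0, n_fragments = 0, seed = 1,
                         decoy_fraction = 0.005) {
  abort_if(!inherits(fixture, "community_fixture"), "not a community_fixture")
  abort_if(n_paralogs < 0 || n_fragments < 0, "decoy counts must be >= 0")
  if (n_paralogs == 0 && n_fragments == 0) return(fixture)
  ids <- fixture$metadata$sample_id
  ge <- fixture$truth$samples$genome_equivalents
  cvs <- as.numeric(unlist(fixture$config$noise_cv))

  with_seed(seed + 104729L, {
    broken_motif <- function() {
      v <- strsplit(sample(hgca_motif_variants(), 1), "")[[1]]
      i <- sample(c(1L, 3L, 4L, 7L, 8L), 1)  # single-letter positions
      v[i] <- sample(setdiff(AA20, v[i]), 1)
      paste(v, collapse = "")
    }
    specs <- list()
    for (i in seq_len(n_paralogs)) {
      repeat {
        len <- sample(150:300, 1)
        pos <- sample(seq(10L, len - 17L), 1)
        s <- paste0(random_aa_nomotif(pos - 1L), broken_motif(),
                    random_aa_nomotif(len - pos - 7L))
        if (is.na(verify_motif(s))) break
      }
      specs[[length(specs) + 1]] <- list(
        id = sprintf("decoyP%03d", i), aa = s, class = "paralog_decoy")
    }
    for (i in seq_len(n_fragments)) {
      len <- sample(60:99, 1)
      pos <- sample(seq(5L, len - 12L), 1)
      s <- paste0(random_aa_nomotif(pos - 1L),
                  sample(hgca_motif_variants(), 1),
                  random_aa_nomotif(len - pos - 7L))
      specs[[length(specs) + 1]] <- list(
        id = sprintf("decoyF%03d", i), aa = s, class = "fragment_decoy")
    }

    newc <- character(0)
    for (g in specs) {
      dlen <- 3L * nchar(g$aa) + 3L
      cid <- paste0(g$id, "_c1")
      newc[cid] <- random_dna(dlen + 40L)
      fixture$genes <- rbind(fixture$genes, data.frame(
        gene_id = g$id, contig_id = cid, start = 21L, end = 20L + dlen,
        strand = "+", stringsAsFactors = FALSE))
      fixture$gene_classes <- rbind(fixture$gene_classes, data.frame(
        gene_id = g$id, taxon_id = "", class = g$class, marker_family = "",
        motif_start = NA_real_, stringsAsFactors = FALSE))
      fixture$proteins <- c(fixture$proteins,
                            Biostrings::AAStringSet(stats::setNames(g$aa, g$id)))
      row <- data.frame(gene_id = g$id, length_bp = dlen,
                        stringsAsFactors = FALSE)
      for (s in seq_along(ids))
        row[[ids[s]]] <- ge[s] * decoy_fraction * lnorm_noise(1, cvs[s])
      fixture$depths <- rbind(fixture$depths, row)
    }
    fixture$contigs <- c(fixture$contigs, Biostrings::DNAStringSet(newc))
    fixture$config$n_paralog_decoys <- n_paralogs
    fixture$config$n_fragment_decoys <- n_fragments
    fixture
  })
}

#' Write a fixture bundle to plain-text files
#'
#' Emits `contigs.fna`, `proteins.faa`, `genes.tsv`, `gene_classes.tsv`,
#' `depths.tsv` (wide, one mean-depth column per sample), `metadata.tsv`,
#' `markers.txt`, `truth_samples.tsv`, `truth_genes.tsv`, `truth_taxa.tsv`
#' and `run_config.json`. Output bytes are a pure function of the fixture.
#' @param fixture A `community_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  abort_if(!inherits(fixture, "community_fixture"), "not a community_fixture")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(fixture$contigs, p("contigs.fna"), width = 80)
  Biostrings::writeXStringSet(fixture$proteins, p("proteins.faa"), width = 80)
  write_tsv(fixture$genes, p("genes.tsv"))
  write_tsv(fixture$gene_classes, p("gene_classes.tsv"))
  write_tsv(fixture$depths, p("depths.tsv"))
  write_tsv(fixture$metadata, p("metadata.tsv"))
  writeLines(fixture$markers, p("markers.txt"))
  write_tsv(fixture$truth$samples, p("truth_samples.tsv"))
  write_tsv(fixture$truth$genes, p("truth_genes.tsv"))
  write_tsv(fixture$truth$taxa, p("truth_taxa.tsv"))
  jsonlite::write_json(fixture$config, p("run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
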
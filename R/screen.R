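# Candidate validation cascade for putative HgcA proteins:
# e-value gate -> cap-helix motif -> length filter -> redundancy collapse,
# with taxonomy attachment and the tandem-hgcB neighbourhood check.

#' The degenerate cap-helix motif as a regular expression
#'
#' HgcA proteins carry a conserved 8-residue span, N-(V/I)-W-C-(A/S)-(A/G)-G-K,
#' in the "cap helix" of the globular domain; its cysteine coordinates the
#' cobalamin cofactor during methyl transfer. The ambiguity code X never
#' matches a constrained position.
#' @return A character scalar usable with [regexpr()].
#' @export
hgca_motif_regex <- function() "N[VI]WC[AS][AG]GK"

#' All 8-mers accepted by the cap-helix motif
#' @return Character vector of the 8 accepted strings.
#' @export
hgca_motif_variants <- function() {
  g <- expand.grid(p2 = c("V", "I"), p5 = c("A", "S"), p6 = c("A", "G"),
                   stringsAsFactors = FALSE)
  sort(paste0("N", g$p2, "W", "C", g$p5, g$p6, "G", "K"))
}

#' Locate the cap-helix motif in amino-acid sequences
#'
#' @param aa_sequence Character vector of uppercase protein sequences.
#' @return Integer vector: 1-based index of the first motif occurrence,
#'   `NA` where the motif is absent (including empty sequences).
#' @examples
#' verify_motif(c("MKNVWCAAGKL", "NIWCSGGK", "NLWCAAGK"))
#' @export
verify_motif <- function(aa_sequence) {
  aa_sequence <- as.character(aa_sequence)
  pos <- regexpr(hgca_motif_regex(), aa_sequence)
  out <- as.integer(pos)
  out[out < 0L] <- NA_integer_
  out[!nzchar(aa_sequence) | is.na(aa_sequence)] <- NA_integer_
  out
}

#' Build a candidate table from protein sequences and gene coordinates
#'
#' @param proteins An [Biostrings::AAStringSet] (or named character vector)
#'   keyed by gene id.
#' @param genes Data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates).
#' @param hits Optional data frame with columns `gene_id`, `evalue`
#'   (e.g. parsed from an HMMER tblout).
#' @return Candidate data frame with one row per protein present in `genes`.
#' @export
candidate_table <- function(proteins, genes, hits = NULL) {
  aa <- as.character(proteins)
  abort_if(is.null(names(aa)) || anyNA(names(aa)),
           "protein sequences must be named by gene id")
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  abort_if(!all(need %in% names(genes)),
           "gene table must have columns: %s", paste(need, collapse = ", "))
  abort_if(any(genes$end < genes$start), "gene table has end < start")
  idx <- match(genes$gene_id, names(aa))
  abort_if(anyNA(idx), "proteins missing for %d gene(s)", sum(is.na(idx)))
  cand <- data.frame(
    gene_id = genes$gene_id, contig_id = genes$contig_id,
    start = as.integer(genes$start), end = as.integer(genes$end),
    strand = as.character(genes$strand),
    aa_sequence = toupper(unname(aa[idx])),
    evalue = NA_real_, stringsAsFactors = FALSE)
  abort_if(!all(grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", cand$aa_sequence)),
           "protein sequences contain non amino-acid letters")
  if (!is.null(hits) && nrow(hits)) {
    abort_if(!all(c("gene_id", "evalue") %in% names(hits)),
             "hit table needs columns gene_id, evalue")
    m <- match(cand$gene_id, hits$gene_id)
    cand$evalue <- as.numeric(hits$evalue[m])
  }
  cand
}

#' Gate candidates on profile-HMM inclusion e-value
#'
#' Candidates whose e-value exceeds the threshold are removed; candidates
#' without an e-value (motif-anchored discovery mode, no HMM search run)
#' pass through unchanged.
#'
#' @param candidates Candidate data frame (see [candidate_table()]).
#' @param threshold Inclusion e-value ceiling; default `1e-25`, the marker
#'   database protocol's recommended inclusion cutoff.
#' @export
gate_by_evalue <- function(candidates, threshold = 1e-25) {
  abort_if(!is.numeric(threshold) || threshold <= 0, "threshold must be > 0")
  ev <- candidates$evalue
  abort_if(any(!is.na(ev) & ev < 0), "negative e-values in input")
  candidates[is.na(ev) | ev <= threshold, , drop = FALSE]
}

#' Drop candidates shorter than a minimum protein length
#'
#' Sequences shorter than `min_aa` residues are discarded; the boundary is
#' strict, so a 100-aa sequence is retained under the default.
#' @export
filter_length <- function(candidates, min_aa = 100) {
  abort_if(min_aa < 1, "min_aa must be >= 1")
  candidates[nchar(candidates$aa_sequence) >= min_aa, , drop = FALSE]
}

#' Collapse identical and contained sequences to one representative
#'
#' Mirrors 100%-identity clustering with containment (word size 5, identity
#' 1.0): two sequences share a cluster when they are identical or one is an
#' exact substring of the other. The representative is the longest member,
#' ties broken by lexicographically smallest `gene_id`.
#'
#' @param candidates Candidate data frame with `gene_id`, `aa_sequence`.
#' @return The input with `cluster_id` (the representative's gene id) and
#'   `is_representative` columns added, rows ordered as processed
#'   (length-descending, then gene id).
#' @export
dedup_identical <- function(candidates) {
  abort_if(nrow(candidates) == 0, "empty candidate set")
  o <- order(-nchar(candidates$aa_sequence), candidates$gene_id)
  x <- candidates[o, , drop = FALSE]
  rep_seq <- character(0); rep_id <- character(0)
  cluster <- character(nrow(x)); isrep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- x$aa_sequence[i]
    hit <- 0L
    for (j in seq_along(rep_seq)) {   # longest-first: s can only be contained
      if (grepl(s, rep_seq[j], fixed = TRUE)) { hit <- j; break }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, s); rep_id <- c(rep_id, x$gene_id[i])
      cluster[i] <- x$gene_id[i]; isrep[i] <- TRUE
    } else {
      cluster[i] <- rep_id[hit]
    }
  }
  x$cluster_id <- cluster
  x$is_representative <- isrep
  rownames(x) <- NULL
  x
}

#' Greedy representative selection at a global-identity threshold
#'
#' Longest-first greedy clustering: each sequence joins the first existing
#' representative with which its global pairwise identity is at least
#' `identity`, where identity = aligned matches / length of the shorter
#' sequence under a Needleman-Wunsch global alignment; otherwise it founds
#' a new cluster. Emulates 50%-identity clustering for picking structure
#' representatives.
#'
#' @param sequences Named character vector (or `AAStringSet`) of proteins.
#' @param identity Identity threshold in (0, 1]; default 0.5.
#' @return Data frame `seq_id`, `cluster_id`, `is_representative`.
#' @export
select_representatives <- function(sequences, identity = 0.5) {
  abort_if(identity <= 0 || identity > 1, "identity must be in (0, 1]")
  aa <- if (is.character(sequences)) sequences else as.character(sequences)
  abort_if(is.null(names(aa)), "sequences must be named")
  abort_if(length(aa) == 0, "empty sequence set")
  o <- order(-nchar(aa), names(aa))
  aa <- aa[o]
  reps <- integer(0)
  cluster <- character(length(aa))
  for (i in seq_along(aa)) {
    assigned <- NA_integer_
    for (r in reps) {
      if (pairwise_identity(aa[[i]], aa[[r]]) >= identity) { assigned <- r; break }
    }
    if (is.na(assigned)) { reps <- c(reps, i); cluster[i] <- names(aa)[i] }
    else cluster[i] <- names(aa)[assigned]
  }
  data.frame(seq_id = names(aa), cluster_id = cluster,
             is_representative = names(aa) == cluster,
             stringsAsFactors = FALSE)
}

#' Global pairwise identity relative to the shorter sequence
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open 10,
#' gap extend 0.5); identity = matched positions / min(sequence lengths).
#' @export
pairwise_identity <- function(a, b) {
  letters25 <- c(AA20, "X", "B", "Z", "J", "U")
  mat <- matrix(-1, length(letters25), length(letters25),
                dimnames = list(letters25, letters25))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Tandem hgcB check downstream of an hgcA gene
#'
#' HgcB is a short ferredoxin-like protein (typically under 100 aa) with two
#' tandem CX2CX2CX3C cysteine motifs, encoded immediately downstream of hgcA
#' on the same strand. Returns the gene id of the closest neighbour
#' satisfying: same contig and strand, start within `max_gap` bp downstream
#' of the hgcA stop (strand-aware), protein shorter than `max_aa` residues,
#' and at least two non-overlapping CX2CX2CX3C matches.
#'
#' @param hgcA Single-row candidate data frame (the validated hgcA gene).
#' @param neighbors Candidate data frame of genes on the same contig.
#' @param max_gap Maximum intergenic distance in bp (default 500).
#' @param max_aa hgcB length ceiling in residues, strict (default 100).
#' @return The paired gene id, or `NA_character_` when none qualifies.
#' @export
check_hgcB <- function(hgcA, neighbors, max_gap = 500, max_aa = 100) {
  abort_if(nrow(hgcA) != 1, "hgcA must be a single gene record")
  if (nrow(neighbors) == 0) return(NA_character_)
  abort_if(!all(neighbors$contig_id == hgcA$contig_id),
           "neighbors must share the hgcA contig")
  nb <- neighbors[neighbors$strand == hgcA$strand &
                  neighbors$gene_id != hgcA$gene_id, , drop = FALSE]
  if (nrow(nb) == 0) return(NA_character_)
  if (hgcA$strand == "+") {
    gap <- nb$start - hgcA$end - 1L
  } else {
    gap <- hgcA$start - nb$end - 1L
  }
  nb <- nb[gap >= 0 & gap <= max_gap, , drop = FALSE]
  gap <- gap[gap >= 0 & gap <= max_gap]
  if (nrow(nb) == 0) return(NA_character_)
  ok <- nchar(nb$aa_sequence) < max_aa &
    vapply(nb$aa_sequence, function(s) {
      m <- gregexpr("C.{2}C.{2}C.{3}C", s)[[1]]
      length(m) >= 2 && m[1] > 0
    }, logical(1))
  nb <- nb[ok, , drop = FALSE]; gap <- gap[ok]
  if (nrow(nb) == 0) return(NA_character_)
  nb$gene_id[order(gap, nb$gene_id)][1]
}

#' Attach taxonomy to a gene from a bin map or a best-hit table
#'
#' Genome-bin (MAG) membership takes precedence: a gene binned into a MAG
#' inherits the MAG's taxonomy. Otherwise the top-ranked row of the
#' best-hit (e.g. BLASTp) table is used; otherwise "unassigned".
#'
#' @param gene_id Gene identifier (scalar).
#' @param bin_map Data frame `gene_id`, `bin_id`, `taxonomy` (may be empty).
#' @param best_hit Data frame `gene_id`, `taxonomy`, `rank` (smaller rank =
#'   better hit; may be empty).
#' @return List with `taxonomy_label` and `taxonomy_source`
#'   (one of "bin_map", "best_hit", "unassigned").
#' @export
assign_taxonomy <- function(gene_id, bin_map = NULL, best_hit = NULL) {
  if (!is.null(bin_map) && nrow(bin_map)) {
    rows <- bin_map[bin_map$gene_id == gene_id, , drop = FALSE]
    if (nrow(rows)) {
      abort_if(length(unique(rows$taxonomy)) > 1,
               "conflicting bin-map taxonomy for gene %s", gene_id)
      return(list(taxonomy_label = rows$taxonomy[1], taxonomy_source = "bin_map"))
    }
  }
  if (!is.null(best_hit) && nrow(best_hit)) {
    rows <- best_hit[best_hit$gene_id == gene_id, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$rank), , drop = FALSE]
      return(list(taxonomy_label = rows$taxonomy[1], taxonomy_source = "best_hit"))
    }
  }
  list(taxonomy_label = "unassigned", taxonomy_source = "unassigned")
}

#' Run the full HgcA validation cascade
#'
#' Applies, in order: the e-value gate, the cap-helix motif check, the
#' 100-aa length filter, and identity/containment deduplication, then
#' attaches taxonomy. Per-stage removal counts are reported via [message()]
#' and returned as the `"stage_counts"` attribute.
#'
#' @param candidates Candidate data frame (see [candidate_table()]).
#' @param evalue_threshold Inclusion e-value ceiling (default 1e-25).
#' @param min_aa Minimum protein length (default 100).
#' @param bin_map,best_hit Optional taxonomy tables (see [assign_taxonomy()]).
#' @param verbose Emit per-stage counts (default TRUE).
#' @return Data frame of validated representatives, one per redundancy
#'   cluster, sorted by gene id: `gene_id`, `aa_sequence`, `motif_start`,
#'   `cluster_id`, `cluster_size`, `taxonomy_label`, `taxonomy_source`.
#' @export
screen <- function(candidates, evalue_threshold = 1e-25, min_aa = 100,
                   bin_map = NULL, best_hit = NULL, verbose = TRUE) {
  n0 <- nrow(candidates)
  g <- gate_by_evalue(candidates, evalue_threshold)
  g$motif_start <- verify_motif(g$aa_sequence)
  m <- g[!is.na(g$motif_start), , drop = FALSE]
  l <- filter_length(m, min_aa)
  counts <- c(input = n0, evalue_gate = nrow(g), motif = nrow(m),
              length = nrow(l))
  if (nrow(l) == 0) {
    out <- data.frame(gene_id = character(0), aa_sequence = character(0),
                      motif_start = integer(0), cluster_id = character(0),
                      cluster_size = integer(0), taxonomy_label = character(0),
                      taxonomy_source = character(0), stringsAsFactors = FALSE)
    counts <- c(counts, nonredundant = 0L)
    attr(out, "stage_counts") <- counts
    return(out)
  }
  d <- dedup_identical(l)
  reps <- d[d$is_representative, , drop = FALSE]
  csize <- table(d$cluster_id)
  tax <- lapply(reps$gene_id, assign_taxonomy, bin_map = bin_map,
                best_hit = best_hit)
  out <- data.frame(
    gene_id = reps$gene_id, aa_sequence = reps$aa_sequence,
    motif_start = reps$motif_start,
    cluster_id = reps$cluster_id,
    cluster_size = as.integer(csize[reps$cluster_id]),
    taxonomy_label = vapply(tax, `[[`, "", "taxonomy_label"),
    taxonomy_source = vapply(tax, `[[`, "", "taxonomy_source"),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- c(counts, nonredundant = nrow(out))
  if (verbose)
    message(sprintf(
      "screen: %d candidates -> %d after e-value gate -> %d with motif -> %d >= %d aa -> %d nonredundant",
      counts["input"], counts["evalue_gate"], counts["motif"],
      counts["length"], min_aa, counts["nonredundant"]))
  attr(out, "stage_counts") <- counts
  out
}
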
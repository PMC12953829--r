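# Length-normalized gene coverage, genome-equivalent estimation and the
# relative-abundance statistic: gene coverage / genome equivalent x 100%,
# read as "percent of genomes in the sample carrying the gene".

#' Coverage records from a depth table
#'
#' Accepts the wide, jgi-style summary dialect: `gene_id`, `length_bp`, one
#' mean-depth column per sample (as produced by
#' jgi_summarize_bam_contig_depths or by [build_community()]).
#'
#' @param depths Wide depth data frame.
#' @param samples Optional subset of sample columns to keep.
#' @return Long data frame `gene_id`, `sample_id`, `gene_length`,
#'   `mean_depth`.
#' @export
coverage_from_depth_table <- function(depths, samples = NULL) {
  abort_if(!all(c("gene_id", "length_bp") %in% names(depths)),
           "depth table needs columns gene_id, length_bp")
  scols <- setdiff(names(depths), c("gene_id", "length_bp"))
  if (!is.null(samples)) {
    abort_if(!all(samples %in% scols), "unknown sample column(s)")
    scols <- samples
  }
  abort_if(length(scols) == 0, "depth table has no sample columns")
  abort_if(any(depths$length_bp <= 0), "gene_length must be > 0")
  out <- do.call(rbind, lapply(scols, function(s) data.frame(
    gene_id = depths$gene_id, sample_id = s,
    gene_length = as.integer(depths$length_bp),
    mean_depth = as.numeric(depths[[s]]), stringsAsFactors = FALSE)))
  abort_if(any(out$mean_depth < 0), "mean_depth must be >= 0")
  rownames(out) <- NULL
  out
}

#' Coverage records from read alignments
#'
#' Computes, for every gene interval, the total number of aligned bases
#' (CIGAR M/=/X blocks of primary alignments) overlapping the interval,
#' divided by the gene length. SAM input is converted on the fly; BAM is
#' read directly. Genes whose interval extends beyond their contig are
#' dropped with a warning.
#'
#' @param path Path to a SAM or BAM file with `@SQ` headers.
#' @param genes Gene table (`gene_id`, `contig_id`, `start`, `end`,
#'   `strand`).
#' @param sample_id Sample label for the output records.
#' @return Long data frame as in [coverage_from_depth_table()].
#' @export
coverage_from_alignments <- function(path, genes, sample_id = "sample1") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  seqinfo <- GenomeInfoDb::seqlengths(gal)

  abort_if(!all(genes$contig_id %in% names(seqinfo)),
           "gene table names contigs absent from the alignment header")
  clen <- seqinfo[genes$contig_id]
  bad <- genes$start < 1 | genes$end > clen
  if (any(bad)) {
    warning(sprintf("dropping %d gene(s) outside contig bounds: %s",
                    sum(bad), paste(genes$gene_id[bad], collapse = ", ")))
    genes <- genes[!bad, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(genes$contig_id,
                               IRanges::IRanges(genes$start, genes$end))
  blocks <- GenomicRanges::grglist(gal, drop.D.ranges = TRUE)
  fb <- unlist(blocks, use.names = FALSE)
  ov <- GenomicRanges::findOverlaps(fb, gr)
  w <- GenomicRanges::width(IRanges::pintersect(
    fb[S4Vectors::queryHits(ov)], gr[S4Vectors::subjectHits(ov)]))
  bases <- numeric(nrow(genes))
  agg <- tapply(w, S4Vectors::subjectHits(ov), sum)
  bases[as.integer(names(agg))] <- as.numeric(agg)
  data.frame(gene_id = genes$gene_id, sample_id = sample_id,
             gene_length = as.integer(genes$end - genes$start + 1L),
             mean_depth = bases / (genes$end - genes$start + 1),
             stringsAsFactors = FALSE)
}

#' Genome equivalents from single-copy marker coverage
#'
#' The genome equivalent of a sample — how many genome copies its reads
#' represent — is estimated as the median length-normalized coverage of
#' universal single-copy marker gene families (each present once per
#' genome, so each family's aggregate depth estimates the genome count).
#' The median is robust to a mismapped or collapsed family. Externally
#' computed values (e.g. from a read-sampling estimator) can be supplied
#' downstream instead via `ge_override` of [profile_abundance()].
#'
#' @param marker_cov Long coverage data frame restricted to marker
#'   families (`gene_id`, `sample_id`, `mean_depth`).
#' @param min_markers Minimum families required per sample (default 3).
#' @return Data frame `sample_id`, `genome_equivalents`, `n_markers`.
#' @export
estimate_genome_equivalents <- function(marker_cov, min_markers = 3) {
  abort_if(nrow(marker_cov) == 0, "no marker coverage records")
  sp <- split(marker_cov$mean_depth, marker_cov$sample_id)
  n <- vapply(sp, length, integer(1))
  abort_if(any(n < min_markers),
           paste("fewer than %d marker genes in sample(s) %s;",
                 "supply genome equivalents explicitly"),
           min_markers, paste(names(sp)[n < min_markers], collapse = ", "))
  data.frame(sample_id = names(sp),
             genome_equivalents = vapply(sp, stats::median, numeric(1)),
             n_markers = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative abundance of genes as percent of genomes
#'
#' `rel_abundance_pct = mean_depth / genome_equivalents x 100`: the
#' percentage of genomes in the metagenome carrying the gene.
#'
#' @param cov Long coverage data frame (`gene_id`, `sample_id`,
#'   `mean_depth`).
#' @param ge Data frame `sample_id`, `genome_equivalents` (> 0).
#' @return Data frame `gene_id`, `sample_id`, `rel_abundance_pct`.
#' @export
relative_abundance <- function(cov, ge) {
  abort_if(any(ge$genome_equivalents <= 0), "genome equivalents must be > 0")
  m <- match(cov$sample_id, ge$sample_id)
  abort_if(anyNA(m), "samples missing genome equivalents: %s",
           paste(unique(cov$sample_id[is.na(m)]), collapse = ", "))
  data.frame(gene_id = cov$gene_id, sample_id = cov$sample_id,
             rel_abundance_pct = 100 * cov$mean_depth /
               ge$genome_equivalents[m],
             stringsAsFactors = FALSE)
}

#' Aggregate relative abundances
#'
#' Sums `rel_abundance_pct` within groups; the grand total per sample
#' always equals the sum of the group totals.
#'
#' @param records Abundance data frame, optionally carrying
#'   `taxonomy_label`, `zone`, `lifestyle` columns.
#' @param by Grouping columns, a subset of
#'   `c("taxonomy_label", "sample_id", "zone", "lifestyle")`.
#' @return Aggregated data frame with a `rel_abundance_pct` sum column.
#' @export
aggregate_abundance <- function(records, by = c("taxonomy_label", "sample_id")) {
  if (nrow(records) == 0)
    return(stats::setNames(
      data.frame(matrix(ncol = length(by) + 1, nrow = 0)),
      c(by, "rel_abundance_pct")))
  abort_if(!all(by %in% names(records)),
           "grouping column(s) absent: %s",
           paste(setdiff(by, names(records)), collapse = ", "))
  f <- stats::as.formula(paste("rel_abundance_pct ~", paste(by, collapse = "+")))
  out <- stats::aggregate(f, data = records, FUN = sum)
  out[do.call(order, out[by]), , drop = FALSE]
}

#' End-to-end abundance profile from a depth table
#'
#' Splits the depth table into marker families and target genes, estimates
#' genome equivalents (unless overridden) and returns per-gene relative
#' abundances.
#'
#' @param depths Wide depth table (see [coverage_from_depth_table()]).
#' @param marker_ids Gene ids of the single-copy marker families.
#' @param gene_ids Target gene ids; default: every non-marker row.
#' @param ge_override Optional data frame `sample_id`,
#'   `genome_equivalents` replacing the marker-based estimate.
#' @return List with `abundance` (long), `genome_equivalents`, `coverage`.
#' @export
profile_abundance <- function(depths, marker_ids, gene_ids = NULL,
                              ge_override = NULL) {
  cov <- coverage_from_depth_table(depths)
  if (is.null(gene_ids)) gene_ids <- setdiff(depths$gene_id, marker_ids)
  ge <- ge_override %||%
    estimate_genome_equivalents(cov[cov$gene_id %in% marker_ids, , drop = FALSE])
  ab <- relative_abundance(cov[cov$gene_id %in% gene_ids, , drop = FALSE], ge)
  list(abundance = ab, genome_equivalents = ge,
       coverage = cov[cov$gene_id %in% gene_ids, , drop = FALSE])
}
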
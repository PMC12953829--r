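# Depth-zone classification, size-fraction lifestyle labels, PA-vs-FL
# habitat-preference scores and dominant-methylator rankings.

#' Classify water depth into a redox zone
#'
#' The water column is grouped as "surface" (<= 50 m, oxic), "intermediate"
#' (50-100 m, suboxic) and "deep" (> 100 m, anoxic; dissolved oxygen is
#' undetectable below 100 m). The unsampled 50-60 m and 100-105 m gaps are
#' closed by extending surface to <= 50 and deep to > 100, so that
#' \[0, 300\] is partitioned with no gaps or overlaps.
#'
#' @param depth Numeric vector of depths in m, each within \[0, 300\].
#' @return Character vector of zone labels.
#' @examples classify_zone(c(0, 30, 50, 90, 120, 140, 170))
#' @export
classify_zone <- function(depth) {
  abort_if(any(!is.finite(depth)), "non-finite depth")
  abort_if(any(depth < 0), "negative depth")
  abort_if(any(depth > 300), "depth beyond 300 m")
  ifelse(depth <= 50, "surface", ifelse(depth <= 100, "intermediate", "deep"))
}

#' Lifestyle label from the retaining filter pore size
#'
#' Sequential filtration through a 3-um and then a 0.22-um membrane defines
#' the fractions: organisms retained on the 3-um film are
#' particle-associated (PA), those passing 3 um but retained at 0.22 um are
#' free-living (FL).
#'
#' @param fraction Character vector naming the retaining pore size, e.g.
#'   `"3um"`, `"0.22um"` (a `u`/micro sign and spaces are tolerated).
#' @return Character vector of `"PA"` / `"FL"`.
#' @export
label_lifestyle <- function(fraction) {
  num <- sub("^\\s*([0-9.]+).*$", "\\1", as.character(fraction))
  size <- suppressWarnings(as.numeric(num))
  out <- ifelse(!is.na(size) & size == 3, "PA",
                ifelse(!is.na(size) & size == 0.22, "FL", NA))
  abort_if(anyNA(out), "unknown filter fraction: %s",
           paste(unique(fraction[is.na(out)]), collapse = ", "))
  out
}

#' Particle-associated vs free-living preference score
#'
#' `log2((pa + eps) / (fl + eps))` for paired percentage abundances of one
#' gene or taxon at one depth. The symmetric pseudocount `eps` engages only
#' when one of the two values is zero (a finite ratio needs a stated
#' policy; a ratio of two positive abundances does not). It defaults to
#' half the smaller nonzero value of the pair; when scoring many features
#' of a sample pair, pass the sample-wide `eps` (half the smallest nonzero
#' abundance across both samples, see [preference_table()]) so that scores
#' share one policy. Both values zero gives score 0 with status "absent".
#'
#' @param pa_pct,fl_pct Non-negative percentage abundances (vectorized).
#' @param eps Pseudocount; `NULL` for the per-pair default.
#' @return Data frame `log2_pa_fl`, `pa_pct`, `fl_pct`, `status`
#'   ("ok"/"absent").
#' @examples
#' habitat_preference(2, 1)          # +1
#' habitat_preference(2.36, 0.07)    # ~= 5.08
#' @export
habitat_preference <- function(pa_pct, fl_pct, eps = NULL) {
  abort_if(any(pa_pct < 0) || any(fl_pct < 0), "abundances must be >= 0")
  n <- max(length(pa_pct), length(fl_pct))
  pa <- rep_len(pa_pct, n); fl <- rep_len(fl_pct, n)
  if (is.null(eps)) {
    eps <- vapply(seq_len(n), function(i) {
      nz <- c(pa[i], fl[i]); nz <- nz[nz > 0]
      if (length(nz)) min(nz) / 2 else 0
    }, numeric(1))
  } else eps <- rep_len(eps, n)
  eps <- ifelse(pa > 0 & fl > 0, 0, eps)   # pseudocount only rescues zeros
  absent <- pa == 0 & fl == 0
  score <- ifelse(absent, 0, log2((pa + eps) / (fl + eps)))
  data.frame(log2_pa_fl = score, pa_pct = pa, fl_pct = fl,
             status = ifelse(absent, "absent", "ok"),
             stringsAsFactors = FALSE)
}

#' Habitat-preference table across paired PA/FL samples
#'
#' Joins a long abundance table to sample metadata, pairs the PA and FL
#' samples at each depth, and scores every gene with [habitat_preference()]
#' using a shared pseudocount per depth pair: half the smallest nonzero
#' abundance observed across the two samples.
#'
#' @param abundance Long data frame `gene_id`, `sample_id`,
#'   `rel_abundance_pct`.
#' @param metadata Data frame `sample_id`, `depth_m`, `fraction`.
#' @return Data frame `gene_id`, `depth_m`, `pa_pct`, `fl_pct`,
#'   `log2_pa_fl`, `status`.
#' @export
preference_table <- function(abundance, metadata) {
  metadata$lifestyle <- label_lifestyle(metadata$fraction)
  out <- list()
  for (d in sort(unique(metadata$depth_m))) {
    pa_id <- metadata$sample_id[metadata$depth_m == d & metadata$lifestyle == "PA"]
    fl_id <- metadata$sample_id[metadata$depth_m == d & metadata$lifestyle == "FL"]
    if (length(pa_id) != 1 || length(fl_id) != 1) next
    sub <- abundance[abundance$sample_id %in% c(pa_id, fl_id), , drop = FALSE]
    if (!nrow(sub)) next
    genes <- sort(unique(sub$gene_id))
    pa <- fl <- stats::setNames(numeric(length(genes)), genes)
    s <- sub[sub$sample_id == pa_id, ]; pa[s$gene_id] <- s$rel_abundance_pct
    s <- sub[sub$sample_id == fl_id, ]; fl[s$gene_id] <- s$rel_abundance_pct
    nz <- c(pa, fl); nz <- nz[nz > 0]
    eps <- if (length(nz)) min(nz) / 2 else 0
    hp <- habitat_preference(pa, fl, eps = eps)
    out[[length(out) + 1]] <- cbind(
      data.frame(gene_id = genes, depth_m = d, stringsAsFactors = FALSE),
      hp[, c("pa_pct", "fl_pct", "log2_pa_fl", "status")])
  }
  if (!length(out)) return(data.frame(
    gene_id = character(0), depth_m = numeric(0), pa_pct = numeric(0),
    fl_pct = numeric(0), log2_pa_fl = numeric(0), status = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top abundant hgcA homologues per sample
#'
#' Stable descending sort by relative abundance within each sample, ties
#' broken by gene id; the first `top_k` rows per sample are returned.
#'
#' @param abundance Long data frame `gene_id`, `sample_id`,
#'   `rel_abundance_pct`.
#' @param top_k Number of genes to keep per sample (>= 1).
#' @return Data frame with a `rank` column added.
#' @export
dominant_methylators <- function(abundance, top_k = 5) {
  abort_if(top_k < 1, "top_k must be >= 1")
  out <- list()
  for (s in sort(unique(abundance$sample_id))) {
    sub <- abundance[abundance$sample_id == s, , drop = FALSE]
    sub <- sub[order(-sub$rel_abundance_pct, sub$gene_id), , drop = FALSE]
    sub <- utils::head(sub, top_k)
    sub$rank <- seq_len(nrow(sub))
    out[[length(out) + 1]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-depth carrier-percentage profile
#'
#' Sums hgcA relative abundance within each sample and annotates depth,
#' zone and lifestyle: the depth-profile data product.
#'
#' @inheritParams preference_table
#' @return Data frame `sample_id`, `depth_m`, `zone`, `lifestyle`,
#'   `total_pct`, ordered by depth then lifestyle.
#' @export
zonation_profile <- function(abundance, metadata) {
  tot <- stats::aggregate(rel_abundance_pct ~ sample_id, data = abundance, sum)
  m <- merge(metadata, tot, by = "sample_id", all.x = TRUE)
  m$rel_abundance_pct[is.na(m$rel_abundance_pct)] <- 0
  data.frame(sample_id = m$sample_id, depth_m = m$depth_m,
             zone = classify_zone(m$depth_m),
             lifestyle = label_lifestyle(m$fraction),
             total_pct = m$rel_abundance_pct,
             stringsAsFactors = FALSE)[order(m$depth_m, m$fraction), ]
}
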
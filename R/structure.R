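# Calpha superposition of predicted HgcA models onto a reference:
# least-squares Kabsch fit (proper rotations only), iterative pruning of
# outlier atom pairs, cap-helix localization and model-confidence summaries.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            UNK = "X")

#' Construct a Calpha structure model
#'
#' @param model_id Identifier.
#' @param residues Data frame `residue_index` (strictly increasing
#'   integers), `aa` (one-letter codes), `x`, `y`, `z` (Angstrom),
#'   `confidence` (per-residue, 0-100; the pLDDT convention).
#' @param global_confidence Optional global model confidence in \[0, 1\]
#'   (the pTM convention).
#' @return A `structure_model`.
#' @export
structure_model <- function(model_id, residues, global_confidence = NA_real_) {
  need <- c("residue_index", "aa", "x", "y", "z", "confidence")
  abort_if(!all(need %in% names(residues)), "residues needs columns: %s",
           paste(need, collapse = ", "))
  abort_if(nrow(residues) == 0, "empty residue set")
  abort_if(any(diff(residues$residue_index) <= 0),
           "residue indices must be strictly increasing")
  abort_if(any(!is.finite(as.matrix(residues[, c("x", "y", "z")]))),
           "non-finite coordinates")
  structure(list(model_id = model_id, residues = residues,
                 global_confidence = as.numeric(global_confidence)),
            class = "structure_model")
}

#' Read Calpha records from a PDB file
#'
#' Parses fixed-width `ATOM` records, keeping the CA atom of each residue
#' (alternate location blank or "A"). Per-residue confidence is read from
#' the temperature-factor column — the slot where structure-prediction
#' tools store pLDDT.
#'
#' @param path PDB file.
#' @param model_id Identifier; defaults to the file name.
#' @param global_confidence Optional pTM-like score to attach.
#' @return A [structure_model()].
#' @export
read_pdb_ca <- function(path, model_id = NULL,
                        global_confidence = NA_real_) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM")]
  name <- substr(at, 13, 16)
  alt <- substr(at, 17, 17)
  at <- at[trimws(name) == "CA" & alt %in% c(" ", "A", "")]
  abort_if(length(at) == 0, "no CA atoms in %s", path)
  res3 <- trimws(substr(at, 18, 20))
  df <- data.frame(
    residue_index = as.integer(substr(at, 23, 26)),
    aa = unname(ifelse(res3 %in% names(AA3TO1), AA3TO1[res3], "X")),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    confidence = as.numeric(substr(at, 61, 66)),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df$residue_index), , drop = FALSE]
  structure_model(model_id %||% basename(path), df, global_confidence)
}

#' Write a Calpha-only PDB file
#' @param model A [structure_model()].
#' @param path Output path.
#' @export
write_pdb_ca <- function(model, path) {
  r <- model$residues
  aa1to3 <- stats::setNames(names(AA3TO1), AA3TO1)
  res3 <- unname(ifelse(r$aa %in% names(aa1to3), aa1to3[r$aa], "UNK"))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), res3, r$residue_index, r$x, r$y, r$z, 1.00,
    r$confidence)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Pair Calpha atoms between a model and a reference
#'
#' Pairing comes either from an explicit table (`model_res`, `ref_res`
#' residue indices) or from a 2-sequence gapped alignment (model first,
#' reference second): columns where both sequences are non-gap pair the
#' corresponding residues in order. Unpaired residues are excluded; pairs
#' are ordered by model residue index; fewer than 3 pairs is an error.
#'
#' @param model,reference [structure_model()] objects.
#' @param pairing Data frame `model_res`, `ref_res`, or `NULL`.
#' @param alignment Character vector of 2 aligned sequences (with `-`
#'   gaps), or `NULL`. When both are `NULL`, residues are paired by
#'   identical residue index.
#' @return Data frame of paired coordinates (`model_res`, `ref_res`,
#'   `mx,my,mz`, `rx,ry,rz`).
#' @export
pair_residues <- function(model, reference, pairing = NULL, alignment = NULL) {
  mr <- model$residues; rr <- reference$residues
  if (is.null(pairing) && !is.null(alignment)) {
    abort_if(length(alignment) != 2, "alignment must hold 2 sequences")
    a <- strsplit(alignment[[1]], "")[[1]]
    b <- strsplit(alignment[[2]], "")[[1]]
    abort_if(length(a) != length(b), "aligned sequences differ in length")
    ai <- cumsum(a != "-"); bi <- cumsum(b != "-")
    keep <- a != "-" & b != "-"
    abort_if(max(ai) > nrow(mr) || max(bi) > nrow(rr),
             "alignment longer than structures")
    pairing <- data.frame(model_res = mr$residue_index[ai[keep]],
                          ref_res = rr$residue_index[bi[keep]])
  }
  if (is.null(pairing)) {
    common <- intersect(mr$residue_index, rr$residue_index)
    pairing <- data.frame(model_res = common, ref_res = common)
  }
  abort_if(anyDuplicated(pairing$model_res) > 0 ||
             anyDuplicated(pairing$ref_res) > 0,
           "pairing must be one-to-one")
  im <- match(pairing$model_res, mr$residue_index)
  ir <- match(pairing$ref_res, rr$residue_index)
  abort_if(anyNA(im) || anyNA(ir), "pairing names unknown residues")
  out <- data.frame(model_res = pairing$model_res, ref_res = pairing$ref_res,
                    mx = mr$x[im], my = mr$y[im], mz = mr$z[im],
                    rx = rr$x[ir], ry = rr$y[ir], rz = rr$z[ir])
  out <- out[order(out$model_res), , drop = FALSE]
  abort_if(nrow(out) < 3, "need at least 3 residue pairs")
  rownames(out) <- NULL
  out
}

kabsch_fit <- function(P, Q) {
  # least-squares proper rotation R and translation t with P %*% R + t ~ Q
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  abort_if(sum(sv$d > max(sv$d) * 1e-10) < 2 && max(sv$d) > 0 ||
             max(sv$d) == 0,
           "degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cq - as.numeric(cp %*% R)
  fitted <- sweep(P %*% R, 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, fitted = fitted)
}

#' Optimal rigid superposition of paired Calpha atoms
#'
#' Kabsch/SVD least-squares fit of the model atoms onto the reference
#' atoms; reflections are excluded (the rotation is proper, det +1).
#'
#' @param pairs Pair table from [pair_residues()] (>= 3 non-collinear
#'   pairs).
#' @return A `superposition_result`: `rotation` (3x3, orthonormal,
#'   det +1), `translation`, `rmsd` (Angstrom), `retained_pairs`,
#'   `pruned_pairs` (0), `iterations` (1), `retained` (model residue
#'   indices).
#' @export
kabsch_superpose <- function(pairs) {
  abort_if(nrow(pairs) < 3, "need at least 3 pairs")
  P <- as.matrix(pairs[, c("mx", "my", "mz")])
  Q <- as.matrix(pairs[, c("rx", "ry", "rz")])
  f <- kabsch_fit(P, Q)
  structure(list(rotation = f$rotation, translation = f$translation,
                 rmsd = f$rmsd, retained_pairs = nrow(pairs),
                 pruned_pairs = 0L, iterations = 1L,
                 retained = pairs$model_res),
            class = "superposition_result")
}

#' Superposition with iterative outlier-pair pruning
#'
#' Alternates fitting and pruning: after each Kabsch fit, every pair whose
#' post-fit Calpha distance exceeds `cutoff` is dropped and the remainder
#' refit, until no pair exceeds the cutoff, `max_iter` fits have run, or a
#' drop would leave fewer than 3 pairs (the offending drop is then not
#' applied). Pruning a worst-fitting subset and refitting can only lower
#' the RMSD over the retained set.
#'
#' @param pairs Pair table from [pair_residues()].
#' @param cutoff Post-fit distance cutoff in Angstrom (default 2.0, the
#'   interactive matchmaker default).
#' @param max_iter Fit iteration cap (default 100).
#' @return A `superposition_result` (see [kabsch_superpose()]).
#' @export
prune_and_superpose <- function(pairs, cutoff = 2.0, max_iter = 100) {
  abort_if(nrow(pairs) < 3, "need at least 3 pairs")
  abort_if(cutoff <= 0, "cutoff must be > 0")
  keep <- rep(TRUE, nrow(pairs))
  it <- 0L
  repeat {
    it <- it + 1L
    P <- as.matrix(pairs[keep, c("mx", "my", "mz")])
    Q <- as.matrix(pairs[keep, c("rx", "ry", "rz")])
    f <- kabsch_fit(P, Q)
    d <- sqrt(rowSums((f$fitted - Q)^2))
    over <- d > cutoff
    if (!any(over) || it >= max_iter) break
    if (sum(keep) - sum(over) < 3) break   # stop before the offending drop
    keep[keep] <- !over
  }
  structure(list(rotation = f$rotation, translation = f$translation,
                 rmsd = f$rmsd, retained_pairs = sum(keep),
                 pruned_pairs = sum(!keep), iterations = it,
                 retained = pairs$model_res[keep]),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over %d pairs (%d pruned, %d iteration%s)\n",
              x$rmsd, x$retained_pairs, x$pruned_pairs, x$iterations,
              if (x$iterations == 1) "" else "s"))
  invisible(x)
}

#' Locate the cap-helix motif on a structure model
#'
#' Finds the conserved N(V/I)WC(A/S)(A/G)GK span in the model's sequence
#' and maps it to structure residue indices. If `aa_sequence` is supplied
#' it must agree with the model's residue codes.
#'
#' @param model A [structure_model()].
#' @param aa_sequence Optional sequence to cross-check against the model.
#' @return `c(from, to)` residue indices, or `NULL` when no motif.
#' @export
locate_cap_helix <- function(model, aa_sequence = NULL) {
  seq_model <- paste(model$residues$aa, collapse = "")
  if (!is.null(aa_sequence)) {
    abort_if(!identical(toupper(aa_sequence), seq_model),
             "aa_sequence does not match model residue codes")
  }
  pos <- verify_motif(seq_model)
  if (is.na(pos)) return(NULL)
  idx <- model$residues$residue_index
  c(from = idx[pos], to = idx[pos + 7L])
}

#' Model-confidence summary
#'
#' Mean per-residue confidence (pLDDT-style) overall and within an
#' optional residue-index region, plus a flag raised when the global
#' score (pTM-style) falls below `global_floor` — the floor observed
#' across accepted models (0.73).
#'
#' @param model A [structure_model()].
#' @param region Optional `c(from, to)` residue-index range.
#' @param global_floor Global-confidence flag threshold (default 0.73).
#' @return List `mean_confidence`, `region_mean`, `global_confidence`,
#'   `low_global_confidence`.
#' @export
confidence_summary <- function(model, region = NULL, global_floor = 0.73) {
  r <- model$residues
  region_mean <- NA_real_
  if (!is.null(region)) {
    sel <- r$residue_index >= region[1] & r$residue_index <= region[2]
    abort_if(!any(sel), "region covers no residues")
    region_mean <- mean(r$confidence[sel])
  }
  gc <- model$global_confidence
  list(mean_confidence = mean(r$confidence),
       region_mean = region_mean,
       global_confidence = gc,
       low_global_confidence = !is.na(gc) && gc < global_floor)
}
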
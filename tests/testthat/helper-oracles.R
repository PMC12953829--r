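# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (brute force / direct optimization) and share no code
# with the implementation paths they check.

# --- rigid superposition: direct minimization over Euler angles ----------
euler_rot <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# best achievable rmsd mapping P onto Q, by numerical rotation search
# (translation handled in closed form via centroids)
oracle_rmsd <- function(P, Q, n_starts = 24) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(th) {
    R <- euler_rot(th[1], th[2], th[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  set.seed(42)
  starts <- rbind(matrix(stats::runif(3 * n_starts, -pi, pi), ncol = 3),
                  c(0, 0, 0))
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
    o <- stats::optim(o$par, f, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    if (o$value < best) best <- o$value
  }
  best
}

# --- monophyly: edge-removal / graph-traversal bipartition oracle --------
# For every edge of the unrooted topology, delete it and collect the tips
# of the component not containing an arbitrary anchor; leaf_set is
# monophyletic iff it (or its complement) equals one such tip set.
oracle_monophyletic <- function(tree, leaf_set) {
  tr <- ape::unroot(tree)
  nt <- length(tr$tip.label)
  edges <- tr$edge
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  target <- sort(unique(leaf_set))
  comp <- sort(setdiff(tr$tip.label, target))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    # BFS from b with the edge (a, b) removed
    seen <- logical(max(edges)); seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    if (seen[a]) next   # (a,b) was not a cut edge in this multigraph
    side <- sort(tr$tip.label[which(seen[seq_len(nt)])])
    if (identical(side, target) || identical(side, comp)) return(TRUE)
  }
  FALSE
}

# --- longest common subsequence (upper bound on alignment matches) -------
lcs_length <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  prev <- integer(n + 1)
  for (i in seq_len(m)) {
    cur <- integer(n + 1)
    for (j in seq_len(n)) {
      cur[j + 1] <- if (x[i] == y[j]) prev[j] + 1L
                    else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[n + 1]
}

# --- per-base pileup from a SAM file (reference-consuming CIGAR ops) -----
oracle_gene_depth <- function(sam_path, genes) {
  lines <- readLines(sam_path)
  body <- lines[!startsWith(lines, "@")]
  depth <- new.env()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || bitwAnd(flag, 256L) > 0 ||
        bitwAnd(flag, 2048L) > 0) next
    rname <- f[3]; pos <- as.integer(f[4]); cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    ref <- pos
    cov <- get0(rname, envir = depth, ifnotfound = NULL)
    if (is.null(cov)) cov <- integer(1e6)
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        cov[ref:(ref + n - 1)] <- cov[ref:(ref + n - 1)] + 1L
        ref <- ref + n
      } else if (type %in% c("D", "N")) {
        ref <- ref + n
      }   # I, S, H, P consume no reference
    }
    assign(rname, cov, envir = depth)
  }
  vapply(seq_len(nrow(genes)), function(i) {
    cov <- get0(genes$contig_id[i], envir = depth, ifnotfound = integer(1e6))
    sum(cov[genes$start[i]:genes$end[i]]) / (genes$end[i] - genes$start[i] + 1)
  }, numeric(1))
}

# --- misc fixture builders ----------------------------------------------
random_points <- function(n, spread = 10) {
  matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
}

rigid_transform <- function(P, angle = NULL, shift = NULL) {
  angle <- angle %||% stats::runif(3, -pi, pi)
  shift <- shift %||% stats::runif(3, -20, 20)
  sweep(P %*% t(euler_rot(angle[1], angle[2], angle[3])), 2, shift, `+`)
}

pairs_from_points <- function(P, Q) {
  data.frame(model_res = seq_len(nrow(P)), ref_res = seq_len(nrow(P)),
             mx = P[, 1], my = P[, 2], mz = P[, 3],
             rx = Q[, 1], ry = Q[, 2], rz = Q[, 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_fixture <- function(seed = 11, n_car = 3, n_non = 4, noise_cv = 0.1,
                          designs = NULL) {
  taxa <- community_taxa(n_car, n_non, seed = seed)
  designs <- designs %||% default_sample_designs(noise_cv = noise_cv)
  build_community(taxa, designs, seed = seed)
}

md5_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)),
                  sub(paste0("^", dir, "/?"), "", files))
}
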
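# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Lognormal noise factors with unit mean and a stated coefficient of variation
#' @noRd
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sig2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -sig2 / 2, sdlog = sqrt(sig2))
}

#' Write a data frame as a plain TSV (deterministic bytes for a fixed input)
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv()] or an external tool
#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Random amino-acid backbone with uniform composition over the 20 letters
#' @noRd
random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
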
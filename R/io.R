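# Readers and writers for the plain-text interchange formats the pipeline
# consumes: gene tables, hit tables (plain TSV or HMMER tblout), taxonomy
# maps and the long abundance table.

#' Read a profile-HMM hit table
#'
#' Two dialects: a plain TSV with columns `gene_id` and `evalue`, or the
#' HMMER3 per-target `--tblout` format (whitespace-delimited, `#`
#' comments; the target name is column 1 and the full-sequence e-value
#' column 5). For tblout input, `evalue_column` selects which e-value is
#' gated: `"full"` (column 5, default) or `"domain"` (column 8, the best
#' single domain).
#'
#' @param path File path.
#' @param format `"tsv"` or `"tblout"`; default guesses from content.
#' @param evalue_column For tblout: `"full"` or `"domain"`.
#' @return Data frame `gene_id`, `evalue`.
#' @export
read_hits_table <- function(path, format = c("auto", "tsv", "tblout"),
                            evalue_column = c("full", "domain")) {
  format <- match.arg(format)
  evalue_column <- match.arg(evalue_column)
  lines <- readLines(path)
  if (format == "auto") {
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    format <- if (length(body) && grepl("\t", body[1])) "tsv" else "tblout"
  }
  if (format == "tsv") {
    df <- read_tsv(path)
    abort_if(!all(c("gene_id", "evalue") %in% names(df)),
             "hit TSV needs columns gene_id, evalue")
    return(df[, c("gene_id", "evalue")])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(data.frame(gene_id = character(0), evalue = numeric(0)))
  fields <- strsplit(trimws(body), "\\s+")
  col <- if (evalue_column == "full") 5L else 8L
  data.frame(gene_id = vapply(fields, `[[`, "", 1L),
             evalue = as.numeric(vapply(fields, `[[`, "", col)),
             stringsAsFactors = FALSE)
}

#' Read a gene coordinate table
#'
#' TSV with columns `gene_id`, `contig_id`, `start`, `end`, `strand`
#' (1-based inclusive coordinates, explicit `+`/`-` strand).
#' @param path File path.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  abort_if(!all(need %in% names(df)),
           "gene table needs columns: %s", paste(need, collapse = ", "))
  abort_if(!all(df$strand %in% c("+", "-")), "strand must be + or -")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  abort_if(any(df$end < df$start), "gene table has end < start")
  df
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir Fixture directory.
#' @return List with the same table slots as the in-memory bundle.
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    proteins = Biostrings::readAAStringSet(p("proteins.faa")),
    contigs = if (file.exists(p("contigs.fna")))
      Biostrings::readDNAStringSet(p("contigs.fna")) else NULL,
    genes = read_gene_table(p("genes.tsv")),
    gene_classes = if (file.exists(p("gene_classes.tsv")))
      read_tsv(p("gene_classes.tsv")) else NULL,
    depths = read_tsv(p("depths.tsv")),
    metadata = read_tsv(p("metadata.tsv")),
    markers = readLines(p("markers.txt")),
    truth = if (file.exists(p("truth_samples.tsv"))) list(
      samples = read_tsv(p("truth_samples.tsv")),
      genes = read_tsv(p("truth_genes.tsv")),
      taxa = read_tsv(p("truth_taxa.tsv"))) else NULL)
}
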
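#' Read an evidence table
#'
#' Tab-separated with header columns `marker_id layer feature_type
#' value_kind value is_log temperature_C duration_hours qtl_interval_cM
#' source_id`; optional `chrom pos_start pos_end` enable positional
#' marker-to-gene mapping.
#'
#' @param path file path.
#' @return data frame of evidence records.
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "layer", "feature_type", "value_kind", "value", "source_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(df$is_log)) df$is_log <- as.logical(df$is_log)
  df
}

#' Write an evidence table
#' @param records evidence data frame.
#' @param path output path.
#' @export
write_evidence <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Either a 4+-column TSV (`gene_id chrom start end`) or a GFF3 file (by
#' `.gff`/`.gff3` extension; gene features only, `ID=` attribute as the
#' gene id, parsed with rtracklayer when available).
#'
#' @param path file path.
#' @return data frame with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_annotations <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    df <- data.frame(gene_id = as.character(gr$ID),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df)[1:4] <- c("gene_id", "chrom", "start", "end")
  }
  stopifnot(all(df$start <= df$end))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  df
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id <TAB> term_name <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids; names are term ids,
#'   with the description kept in the `term_name` attribute of each set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) next
    genes <- unique(parts[-(1:2)])
    attr(genes, "term_name") <- parts[2]
    out[[parts[1]]] <- genes
  }
  if (anyDuplicated(names(out))) stop("duplicate term_id in GMT")
  out
}

#' Write gene sets in GMT format
#' @param terms named list of character gene vectors (optionally with a
#'   `term_name` attribute).
#' @param path output path.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id) {
    nm <- attr(terms[[id]], "term_name")
    if (is.null(nm)) nm <- id
    paste(c(id, nm, as.character(terms[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression significance table
#'
#' Two-column TSV `gene_id pvalue` (differential-expression p-value under
#' cold treatment).
#'
#' @param path file path.
#' @return named numeric vector of p-values, names are gene ids.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "pvalue")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  p <- df$pvalue
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("expression p-values must be in (0,1]")
  stats::setNames(p, df$gene_id)
}

#' Write a per-class score matrix to TSV
#'
#' Columns `gene_id`, one per layer, `W`, `combined`.
#'
#' @param m a `gene_score_matrix`.
#' @param path output path.
#' @export
write_score_matrix <- function(m, path) {
  df <- data.frame(gene_id = m$genes, m$S, W = m$W, combined = m$combined,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-class score matrix written by [write_score_matrix()]
#' @param path file path.
#' @param duration_class class label to attach (`"short"`, `"mid"`, `"long"`).
#' @return a `gene_score_matrix`.
#' @export
read_score_matrix <- function(path, duration_class = "short") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  layer_cols <- setdiff(names(df), c("gene_id", "W", "combined"))
  S <- as.matrix(df[, layer_cols, drop = FALSE])
  rownames(S) <- df$gene_id
  new_gene_score_matrix(duration_class, S, df$W, stats::setNames(df$combined, df$gene_id))
}

#' Read a genotype matrix
#'
#' Either a TSV with samples in columns (`marker_id gene_id chrom pos
#' sample1 sample2 ...`, dosages 0/1/2, `NA` for missing) or a VCF
#' (`.vcf`), whose GT field is converted to alt-allele dosage (requires
#' vcfR; gene assignment then needs a separate marker-to-gene map).
#'
#' @param path file path.
#' @return list with `dosage` (markers x samples integer matrix),
#'   `marker_gene` (named character: marker -> gene, possibly `NA`).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      a <- strsplit(g, "[/|]")[[1]]
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a) > 0)
    })
    ids <- vcfR::getID(v)
    ids[is.na(ids)] <- paste0("snp", seq_len(nrow(dos)))[is.na(ids)]
    rownames(dos) <- ids
    mg <- stats::setNames(rep(NA_character_, nrow(dos)), rownames(dos))
    return(list(dosage = dos, marker_gene = mg))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("marker_id", "gene_id", "chrom", "pos"), names(df))
  samp <- setdiff(names(df), meta)
  dos <- as.matrix(df[, samp, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- df$marker_id
  mg <- stats::setNames(
    if ("gene_id" %in% meta) df$gene_id else rep(NA_character_, nrow(df)),
    df$marker_id)
  list(dosage = dos, marker_gene = mg)
}

#' Read a two-column phenotype table (`sample_id label`)
#' @param path file path.
#' @return named character vector of labels.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sample_id", "label")
  stats::setNames(df$label, df$sample_id)
}

#' Read a newline-delimited gene list
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(x[nzchar(trimws(x))])
}
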
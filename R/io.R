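# Tab-delimited readers and writers for every interchange format the
# pipeline touches. Columns are validated on read; coordinates in the gene
# annotation are 1-based inclusive.

read_tsv_checked <- function(path, required) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read/write pipeline tables
#'
#' Tab-delimited readers and writers: SNP tables (chrom, pos, snp, p), LD
#' pairs (snp_a, snp_b, r2), gene annotation (gene, chrom, start, end,
#' strand; 1-based inclusive), count matrices (first column `gene`, one
#' column per sample), sample metadata (sample, group, tissue) and
#' gene-score tables.
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return tibbles (`read_counts` a matrix); writers return
#'   `path` invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
read_snp_table <- function(path) read_tsv_checked(path, c("chrom", "pos", "snp", "p"))

#' @rdname pipeline-io
#' @export
write_snp_table <- function(x, path) { readr::write_tsv(x, path); invisible(path) }

#' @rdname pipeline-io
#' @export
read_ld_table <- function(path) read_tsv_checked(path, c("snp_a", "snp_b", "r2"))

#' @rdname pipeline-io
#' @export
write_ld_table <- function(x, path) { readr::write_tsv(x, path); invisible(path) }

#' @rdname pipeline-io
#' @export
read_gene_annotation <- function(path) {
  x <- read_tsv_checked(path, c("gene", "chrom", "start", "end", "strand"))
  if (any(x$start > x$end)) stop("annotation has start > end", call. = FALSE)
  if (anyDuplicated(x$gene)) stop("duplicate gene symbols in annotation", call. = FALSE)
  x
}

#' @rdname pipeline-io
#' @export
write_gene_annotation <- function(x, path) { readr::write_tsv(x, path); invisible(path) }

#' @rdname pipeline-io
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene") stop("first column of a count table must be `gene`", call. = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- x$gene
  storage.mode(m) <- "integer"
  m
}

#' @rdname pipeline-io
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x, rownames = "gene"), path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_sample_metadata <- function(path) read_tsv_checked(path, c("sample", "group"))

#' @rdname pipeline-io
#' @export
write_sample_metadata <- function(x, path) { readr::write_tsv(x, path); invisible(path) }

#' @rdname pipeline-io
#' @export
read_gene_scores <- function(path) {
  read_tsv_checked(path, c("gene", "n_snps", "k", "p_min", "p_adj", "q", "flagged"))
}

#' @rdname pipeline-io
#' @export
write_gene_scores <- function(x, path) { readr::write_tsv(x, path); invisible(path) }

#' @rdname pipeline-io
#' @export
read_edges <- function(path) read_tsv_checked(path, c("from_node", "to_node", "weight"))

#' @rdname pipeline-io
#' @export
write_edges <- function(x, path) { readr::write_tsv(x, path); invisible(path) }
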
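# Readers/writers for the plain-text interchange formats used throughout:
# TSV matrices (genes/CpGs x samples), BED intervals, GMT gene sets, and
# the JSON truth ledger. All coordinates on disk are 0-based half-open.

#' Read a numeric feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (genes or CpGs). Used for counts, log-CPM and beta-value matrices.
#'
#' @param path file path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2L, "matrix TSV %s needs an id column plus >=1 sample", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name for the feature-id column (default `"feature_id"`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "matrix must have row and column names")
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-annotation TSV (sample_id, label)
#' @param path file path.
#' @return Named character vector: labels named by sample id.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2L, "label TSV %s needs two columns", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write sample labels as a two-column TSV
#' @param labels named character vector (names = sample ids).
#' @param path output path.
#' @param value_col header for the label column.
#' @export
write_labels_tsv <- function(labels, path, value_col = "condition") {
  df <- data.frame(sample_id = names(labels), value = unname(labels),
                   stringsAsFactors = FALSE)
  colnames(df)[2L] <- value_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from a gene-info TSV
#'
#' Columns: gene_id, biotype (lncRNA/coding), chrom, strand (+/-), tss
#' (0-based first transcribed base).
#'
#' @param path file path.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
read_gene_info <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' @rdname read_gene_info
#' @param annot gene annotation data frame.
#' @export
write_gene_info <- function(annot, path) {
  utils::write.table(annot[, c("gene_id", "biotype", "chrom", "strand", "tss")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a gene annotation table
#'
#' Checks the required columns (gene_id, biotype, chrom, strand, tss),
#' id uniqueness, strand values and non-negative TSS, and stamps the
#' `gene_annotation` class.
#'
#' @param df data frame to validate.
#' @return The validated `gene_annotation` data frame.
#' @export
validate_annotation <- function(df) {
  need <- c("gene_id", "biotype", "chrom", "strand", "tss")
  assert_that(all(need %in% colnames(df)),
              "annotation missing columns: %s",
              paste(setdiff(need, colnames(df)), collapse = ", "))
  assert_that(!anyDuplicated(df$gene_id), "gene_id values must be unique")
  assert_that(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  assert_that(all(df$tss >= 0), "tss must be non-negative")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write TSS positions as BED6 (one 1-bp feature per gene)
#' @param annot gene annotation.
#' @param path output path.
#' @export
write_genes_bed <- function(annot, path) {
  bed <- data.frame(annot$chrom, annot$tss, annot$tss + 1L, annot$gene_id,
                    0L, annot$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a CpG map as BED4 (chrom, start, end, cpg_id)
#' @param path file path.
#' @return data.frame with cpg_id, chrom, pos (0-based).
#' @export
read_cpg_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 4L, "CpG BED %s needs 4 columns", path)
  out <- data.frame(cpg_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    pos = as.integer(df[[2L]]), stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(out$cpg_id), "cpg_id values must be unique")
  out
}

#' @rdname read_cpg_bed
#' @param cpgmap CpG map data frame (cpg_id, chrom, pos).
#' @export
write_cpg_bed <- function(cpgmap, path) {
  ord <- order(cpgmap$chrom, cpgmap$pos)  # sorted within chromosome on write
  cpgmap <- cpgmap[ord, , drop = FALSE]
  bed <- data.frame(cpgmap$chrom, cpgmap$pos, cpgmap$pos + 1L, cpgmap$cpg_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    assert_that(length(f) >= 3L, "GMT line with fewer than 3 fields")
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the truth ledger (planted ground truth) as JSON
#'
#' The ledger records every effect the synthetic-cohort generator planted:
#' downregulated genes and their log2 fold changes, hypermethylated
#' promoters and their delta-beta, liver-preferential genes, the
#' liver-signature coding genes, the survival hazard coefficient and the
#' master seed. It round-trips losslessly through JSON.
#'
#' @param path file path.
#' @return A list of class `truth_ledger`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_genes <- unlist(x$de_genes)
  x$hyperm_promoters <- unlist(x$hyperm_promoters)
  class(x) <- "truth_ledger"
  x
}

#' @rdname read_truth
#' @param truth truth ledger list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
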
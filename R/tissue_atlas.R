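# Multi-tissue expression profiling: per-tissue means (with organ
# pooling), liver-preferential vs ubiquitous classification, and the
# fetal-vs-adult liver contrast.

#' Per-gene per-tissue mean expression
#'
#' Averages normalized expression over the replicate samples of each
#' tissue. A pooling map can merge related organs before averaging (e.g.
#' two lung cohorts into "lung", three kidney cohorts into "kidney");
#' pooled means weight each sample equally.
#'
#' @param expr genes x samples expression matrix (CPM or log-CPM; state
#'   which when interpreting downstream thresholds).
#' @param tissue_labels named vector: tissue per sample (all columns of
#'   `expr` must be covered).
#' @param pool optional named list: new tissue name -> character vector
#'   of labels to merge.
#' @return Numeric matrix genes x tissues of mean expression.
#' @export
tissue_means <- function(expr, tissue_labels, pool = NULL) {
  missing <- setdiff(colnames(expr), names(tissue_labels))
  assert_that(length(missing) == 0L, "samples without tissue label: %s",
              paste(utils::head(missing, 5L), collapse = ", "))
  lab <- as.character(tissue_labels[colnames(expr)])
  if (!is.null(pool)) {
    for (nm in names(pool)) lab[lab %in% pool[[nm]]] <- nm
  }
  tissues <- unique(lab)
  out <- vapply(tissues, function(t)
    rowMeans(expr[, lab == t, drop = FALSE]), numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Classify genes as liver-preferential or ubiquitous
#'
#' A gene counts as "expressed at a similar level" in a non-liver tissue
#' when its mean there reaches both the absolute floor `tau` and the
#' fraction `r` of its liver mean (linear CPM scale). Genes with more
#' than `k` such tissues are ubiquitous, the rest liver-preferential.
#' Genes not expressed in liver (`mu_liver < tau`) are labeled ubiquitous
#' with a warning — liver preference is undefined for them.
#'
#' @param mu genes x tissues mean-expression matrix from
#'   [tissue_means()], linear CPM scale.
#' @param liver name of the liver column (default `"liver"`).
#' @param expr_floor absolute expression floor `tau` (default 1 CPM).
#' @param similarity_ratio fraction `r` of the liver mean counting as
#'   similar (> 0; default 0.5).
#' @param k ubiquity threshold: ubiquitous iff similar in more than `k`
#'   non-liver tissues (default 3).
#' @param exclude tissues ignored in the count (default
#'   `"fetal_liver"` — developmental, not an adult organ).
#' @return data.frame of class `tissue_profile`: gene_id, liver_mean,
#'   n_similar_tissues, label.
#' @export
classify_liver_preferential <- function(mu, liver = "liver", expr_floor = 1,
                                        similarity_ratio = 0.5, k = 3L,
                                        exclude = "fetal_liver") {
  assert_that(similarity_ratio > 0, "similarity_ratio must be > 0")
  assert_that(liver %in% colnames(mu), "liver tissue '%s' not present", liver)
  others <- setdiff(colnames(mu), c(liver, exclude))
  liv <- mu[, liver]
  similar <- mu[, others, drop = FALSE] >= expr_floor &
    mu[, others, drop = FALSE] >= similarity_ratio * liv
  n_similar <- rowSums(similar)
  label <- ifelse(n_similar > k, "ubiquitous", "liver_preferential")
  low_liver <- liv < expr_floor
  if (any(low_liver)) {
    warning(sprintf("%d gene(s) below the liver expression floor labeled ubiquitous",
                    sum(low_liver)), call. = FALSE)
    label[low_liver] <- "ubiquitous"
  }
  out <- data.frame(gene_id = rownames(mu), liver_mean = liv,
                    n_similar_tissues = n_similar, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("tissue_profile", "data.frame")
  out
}

#' Fetal-vs-adult liver expression contrast
#'
#' Per gene: `log2((mean fetal + prior) / (mean adult + prior))` on the
#' linear CPM scale plus a two-sided Mann-Whitney p-value. Negative
#' ratios mean reduced fetal expression.
#'
#' @param expr genes x samples CPM matrix.
#' @param fetal_samples,adult_samples column ids (>= 2 each).
#' @param genes optional subset of gene ids (default: all rows).
#' @param prior pseudo-expression offset (default 0.5).
#' @return data.frame: gene_id, log2_ratio, p.
#' @export
fetal_adult_contrast <- function(expr, fetal_samples, adult_samples,
                                 genes = NULL, prior = 0.5) {
  assert_that(length(fetal_samples) >= 2L && length(adult_samples) >= 2L,
              "need >= 2 samples per developmental stage")
  assert_that(all(c(fetal_samples, adult_samples) %in% colnames(expr)),
              "stage sample ids missing from expression matrix")
  if (is.null(genes)) genes <- rownames(expr)
  fe <- expr[genes, fetal_samples, drop = FALSE]
  ad <- expr[genes, adult_samples, drop = FALSE]
  ratio <- log2((rowMeans(fe) + prior) / (rowMeans(ad) + prior))
  p <- vapply(seq_along(genes), function(i) {
    if (stats::sd(c(fe[i, ], ad[i, ])) == 0) return(1)
    suppressWarnings(stats::wilcox.test(fe[i, ], ad[i, ])$p.value)
  }, numeric(1L))
  data.frame(gene_id = genes, log2_ratio = ratio, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}
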
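# Two-group empirical-Bayes moderated-t differential expression, BH FDR,
# and the repeated tumor-subsampling consensus procedure: genes must be
# significant at FDR < 1% in every one of R random tumor draws (against
# all normals) to be retained, and the top set is then selected by
# log2 fold-change and FDR cutoffs on the full-cohort fit.

#' Empirical-Bayes moderated t-test for two groups
#'
#' Per gene, computes the difference of group means on the (log-CPM)
#' expression scale, the pooled residual variance with `n - 2` degrees of
#' freedom, shrinks the gene-wise variances toward a prior variance
#' `s0^2` with prior degrees of freedom `d0` estimated by matching the
#' moments of `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)` (the prior
#' df solves `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` via the
#' inverse trigamma function), and tests
#' `t_g = betahat_g / sqrt(s2_post_g (1/n1 + 1/n2))` against a t
#' distribution with `d0 + d_g` degrees of freedom. `d0 = 0` reproduces
#' the ordinary two-sample t-test; `d0 = Inf` gives a z-like statistic
#' with variance `s0^2` for every gene.
#'
#' @param expr numeric matrix (genes x samples) of normalized expression.
#' @param groups two-level factor/vector over columns; the contrast is
#'   second level minus first level (factor level order).
#' @param d0,s02 optional: force the prior degrees of freedom and prior
#'   variance instead of estimating them.
#' @return A `data.frame` of class `de_result`: gene_id, logfc, s2,
#'   df_resid, s2_post, t, p, q (BH-adjusted); attributes `d0`, `s02`.
#' @examples
#' x <- matrix(rnorm(60), 10, 6)
#' dimnames(x) <- list(paste0("g", 1:10), paste0("s", 1:6))
#' moderated_t(x, rep(c("a", "b"), each = 3))
#' @export
moderated_t <- function(expr, groups, d0 = NULL, s02 = NULL) {
  groups <- factor(groups)
  assert_that(nlevels(groups) == 2L, "groups must have exactly two levels")
  assert_that(length(groups) == ncol(expr),
              "groups length must equal ncol(expr)")
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  assert_that(n1 >= 2L && n2 >= 2L, "each group needs >= 2 samples")

  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  beta <- m2 - m1
  v1 <- row_vars(expr[, g1, drop = FALSE])
  v2 <- row_vars(expr[, g2, drop = FALSE])
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df

  if (is.null(d0) || is.null(s02)) {
    est <- estimate_prior_var(s2, df)
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s02)) s02 <- est$s02
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- df
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- beta / se
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene_id = rownames(expr), logfc = beta, s2 = s2,
                    df_resid = df, s2_post = s2_post, t = tstat, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("de_result", "data.frame")
  out
}

# Moment estimator of the variance prior (d0, s02) from gene-wise sample
# variances s2 with common residual df. Genes with non-finite log(s2)
# (zero variance) are excluded from estimation but still moderated.
estimate_prior_var <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  e <- e[is.finite(e)]
  assert_that(length(e) >= 2L, "need >= 2 genes with positive variance")
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # under-dispersed e: no evidence of variance heterogeneity
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Repeated tumor-subsampling consensus differential expression
#'
#' Runs `R` iterations; each draws `n_tumor_draw` tumor samples without
#' replacement (a fresh draw every iteration), keeps all normal samples,
#' and reruns the whole normalization + test chain on the subsample: TMM
#' factors, log-CPM, moderated t, BH adjustment. A gene counts as
#' significant in an iteration if its q-value is below `fdr_threshold`
#' and (for `direction = "down"`) its log fold change is negative. A gene
#' is retained only if significant in all `R` iterations — the consensus
#' intersection rule.
#'
#' @param counts genes x samples raw count matrix.
#' @param condition named vector over samples with labels `normal_label`
#'   and `tumor_label`.
#' @param n_tumor_draw tumors drawn per iteration (default 50).
#' @param R number of iterations (default 200).
#' @param fdr_threshold per-iteration BH threshold (default 0.01).
#' @param direction `"down"`, `"up"` or `"both"` (default `"down"`:
#'   downregulated in tumor).
#' @param seed integer seed; iteration draws derive from it.
#' @param normal_label,tumor_label condition labels (defaults
#'   `"normal"`/`"tumor"`).
#' @param prior_count log-CPM offset passed through to [log_cpm()].
#' @return A `data.frame` of class `consensus_result`: gene_id,
#'   n_significant (0..R), retained, mean_logFC (average over
#'   iterations); attributes `R`, `fdr_threshold`, `direction`.
#' @export
subsample_consensus <- function(counts, condition, n_tumor_draw = 50L,
                                R = 200L, fdr_threshold = 0.01,
                                direction = c("down", "up", "both"),
                                seed = 1L, normal_label = "normal",
                                tumor_label = "tumor", prior_count = 0.5) {
  direction <- match.arg(direction)
  condition <- condition[colnames(counts)]
  normals <- colnames(counts)[condition == normal_label]
  tumors <- colnames(counts)[condition == tumor_label]
  assert_that(length(tumors) >= n_tumor_draw,
              "n_tumor_draw (%d) exceeds available tumors (%d)",
              n_tumor_draw, length(tumors))
  assert_that(length(normals) >= 2L, "need >= 2 normal samples")
  set.seed(child_seed(seed, "consensus"))

  ng <- nrow(counts)
  n_sig <- integer(ng)
  sum_lfc <- numeric(ng)
  for (r in seq_len(R)) {
    draw <- sample(tumors, n_tumor_draw)
    sub <- counts[, c(normals, draw), drop = FALSE]
    grp <- factor(rep(c(normal_label, tumor_label),
                      c(length(normals), n_tumor_draw)),
                  levels = c(normal_label, tumor_label))
    nf <- tmm_factors(sub)
    lc <- log_cpm(sub, nf, prior_count = prior_count)
    de <- moderated_t(lc, grp)
    sig <- de$q < fdr_threshold
    sig <- switch(direction,
                  down = sig & de$logfc < 0,
                  up = sig & de$logfc > 0,
                  both = sig)
    n_sig <- n_sig + sig
    sum_lfc <- sum_lfc + de$logfc
  }
  out <- data.frame(gene_id = rownames(counts), n_significant = n_sig,
                    retained = n_sig == R, mean_logFC = sum_lfc / R,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "R") <- R
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "direction") <- direction
  class(out) <- c("consensus_result", "data.frame")
  out
}

#' Select the top downregulated consensus genes
#'
#' Among genes retained by the consensus procedure that also satisfy
#' `logFC < logfc_cut` and `q < fdr_cut` in the full-cohort fit, returns
#' the `n_top` most negative by log fold change, most-downregulated
#' first; ties broken by q-value then gene id. If fewer than `n_top`
#' genes qualify, all of them are returned with a warning.
#'
#' @param cr `consensus_result` from [subsample_consensus()].
#' @param de `de_result` on the full cohort, covering the same genes.
#' @param logfc_cut log2 fold-change cutoff (default -3.5).
#' @param fdr_cut full-cohort FDR cutoff (default 0.05).
#' @param n_top number of genes to return (default 35).
#' @return Character vector of gene ids, ascending by logFC.
#' @export
select_top <- function(cr, de, logfc_cut = -3.5, fdr_cut = 0.05,
                       n_top = 35L) {
  assert_that(setequal(cr$gene_id, de$gene_id),
              "consensus and DE results must cover the same genes")
  de <- de[match(cr$gene_id, de$gene_id), ]
  ok <- cr$retained & de$logfc < logfc_cut & de$q < fdr_cut
  cand <- data.frame(gene_id = cr$gene_id[ok], logfc = de$logfc[ok],
                     q = de$q[ok], stringsAsFactors = FALSE)
  cand <- cand[order(cand$logfc, cand$q, cand$gene_id), ]
  if (nrow(cand) < n_top)
    warning(sprintf("only %d genes meet the top-set criteria (requested %d)",
                    nrow(cand), n_top), call. = FALSE)
  utils::head(cand$gene_id, n_top)
}
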
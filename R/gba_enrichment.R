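# Guilt-by-association functional prediction: quartile patient grouping
# on a target lncRNA, coding-gene ranking by log2 fold change between the
# groups, and preranked gene-set enrichment with a gene-label
# permutation null.

#' Top/bottom-quartile patient groups on a target gene
#'
#' The `floor(n/4)` samples with the highest expression of the target
#' form the high group, the lowest `floor(n/4)` the low group. Boundary
#' ties are resolved deterministically by sample id.
#'
#' @param target_expr named numeric vector: target-gene expression per
#'   sample (n >= 8, non-constant).
#' @return List with character vectors `high` and `low`.
#' @export
quartile_groups <- function(target_expr) {
  n <- length(target_expr)
  assert_that(n >= 8L, "need at least 8 samples for quartile grouping")
  assert_that(!is.null(names(target_expr)), "target_expr must be named")
  assert_that(stats::sd(target_expr) > 0,
              "constant target expression: quartile split undefined")
  k <- n %/% 4L
  ord <- order(target_expr, names(target_expr))
  ranked <- names(target_expr)[ord]
  list(high = ranked[seq.int(n - k + 1L, n)], low = ranked[seq_len(k)])
}

#' Rank coding genes by high-vs-low log2 fold change
#'
#' The ranking metric is the plain difference of group means on the
#' log-CPM scale (a log2 fold change), sorted descending; ties are
#' ordered by gene id.
#'
#' @param expr genes x samples normalized (log-CPM) expression restricted
#'   to coding genes.
#' @param high,low sample-id vectors from [quartile_groups()] (>= 2 each).
#' @return data.frame of class `ranked_list`: gene_id, metric, in
#'   ranking order.
#' @export
rank_by_log2fc <- function(expr, high, low) {
  assert_that(length(high) >= 2L && length(low) >= 2L,
              "both groups need >= 2 samples")
  assert_that(nrow(expr) > 0L, "no genes to rank")
  metric <- rowMeans(expr[, high, drop = FALSE]) -
    rowMeans(expr[, low, drop = FALSE])
  ord <- order(-metric, rownames(expr))
  out <- data.frame(gene_id = rownames(expr)[ord], metric = metric[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Weighted Kolmogorov-Smirnov-like running-sum enrichment score for the
# genes at positions idx of a ranked list with |metric| weights w.
gsea_es <- function(n, idx, w, p_w) {
  hit_w <- abs(w[idx])^p_w
  steps <- rep(-1 / (n - length(idx)), n)
  steps[idx] <- hit_w / sum(hit_w)
  cs <- cumsum(steps)
  cs[which.max(abs(cs))]
}

#' Preranked gene-set enrichment with a permutation null
#'
#' For each gene set, the running sum over the ranked list increments at
#' set members by `|metric|^p_w` (normalized over the in-set total) and
#' decrements at non-members by `1/(N - set size)`; the enrichment score
#' (ES) is the extremum. Significance comes from `n_perm` random draws
#' of equally sized gene-label sets: the one-sided permutation p on the
#' side of the observed ES (granularity `1/(n_perm + 1)`), and
#' NES = ES / mean(|permuted ES| of the same sign). q-values are
#' BH-adjusted across sets. Sets with fewer than 2 members in the list
#' are skipped with a warning; a set spanning the entire list is flagged
#' degenerate.
#'
#' @param rl `ranked_list` from [rank_by_log2fc()].
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param p_w metric weight exponent (default 1; 0 = classic KS).
#' @param n_perm permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return data.frame of class `gsea_result`: set_name, size, ES, NES,
#'   p, q, leading_edge (size), degenerate.
#' @export
gsea_preranked <- function(rl, gene_sets, p_w = 1, n_perm = 1000L,
                           seed = 1L) {
  assert_that(n_perm >= 100L, "n_perm must be >= 100")
  assert_that(inherits(rl, "data.frame") && all(c("gene_id", "metric") %in%
                colnames(rl)), "rl must have gene_id and metric columns")
  set.seed(child_seed(seed, "gsea"))
  n <- nrow(rl)
  w <- rl$metric
  rows <- lapply(names(gene_sets), function(nm) {
    idx <- which(rl$gene_id %in% gene_sets[[nm]])
    if (length(idx) < 2L) {
      warning(sprintf("set %s has <2 genes in the ranked list; skipped", nm),
              call. = FALSE)
      return(NULL)
    }
    degenerate <- length(idx) == n
    if (degenerate) {
      return(data.frame(set_name = nm, size = length(idx), ES = NA_real_,
                        NES = NA_real_, p = NA_real_, leading_edge = NA_integer_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    es <- gsea_es(n, idx, w, p_w)
    perm <- vapply(seq_len(n_perm), function(i)
      gsea_es(n, sample.int(n, length(idx)), w, p_w), numeric(1L))
    if (es >= 0) {
      p <- (1 + sum(perm >= es)) / (n_perm + 1)
      denom <- mean(perm[perm > 0])
    } else {
      p <- (1 + sum(perm <= es)) / (n_perm + 1)
      denom <- mean(abs(perm[perm < 0]))
    }
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    # leading edge: hits at or before (after, for negative ES) the extremum
    hit_w <- abs(w[idx])^p_w
    steps <- rep(-1 / (n - length(idx)), n)
    steps[idx] <- hit_w / sum(hit_w)
    peak <- which.max(abs(cumsum(steps)))
    le <- if (es >= 0) sum(idx <= peak) else sum(idx >= peak)
    data.frame(set_name = nm, size = length(idx), ES = es, NES = nes, p = p,
               leading_edge = le, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  assert_that(!is.null(out), "no testable gene set")
  out$q <- NA_real_
  testable <- !out$degenerate
  out$q[testable] <- bh_adjust(out$p[testable])
  out <- out[, c("set_name", "size", "ES", "NES", "p", "q",
                 "leading_edge", "degenerate")]
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' One-call guilt-by-association analysis for a target gene
#'
#' Quartile-splits patients on the target lncRNA, ranks coding genes by
#' high-vs-low log2 fold change, and runs preranked enrichment.
#'
#' @param expr genes x samples log-CPM matrix (target + coding genes).
#' @param target target gene id (must be a row of `expr`).
#' @param coding_genes character vector of coding gene ids to rank.
#' @param gene_sets named list of gene sets.
#' @inheritParams gsea_preranked
#' @return List: `groups`, `ranked` and `gsea` (the `gsea_result`).
#' @export
gba_analysis <- function(expr, target, coding_genes, gene_sets, p_w = 1,
                         n_perm = 1000L, seed = 1L) {
  assert_that(target %in% rownames(expr), "target %s not in matrix", target)
  coding_genes <- setdiff(intersect(coding_genes, rownames(expr)), target)
  assert_that(length(coding_genes) > 0L, "no coding genes available")
  grp <- quartile_groups(expr[target, ])
  rl <- rank_by_log2fc(expr[coding_genes, , drop = FALSE], grp$high, grp$low)
  res <- gsea_preranked(rl, gene_sets, p_w = p_w, n_perm = n_perm, seed = seed)
  list(groups = grp, ranked = rl, gsea = res)
}
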
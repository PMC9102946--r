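# Strand-aware promoter windows, CpG-to-promoter assignment, and
# hypermethylation calling from beta-value matrices. Coordinates are
# 0-based half-open throughout; the promoter is the span strictly
# upstream of the TSS (the TSS base itself is excluded).

#' Strand-aware promoter windows upstream of the TSS
#'
#' For a + strand gene with TSS `t` the window is `[max(0, t - span), t)`;
#' for a - strand gene it is `[t + 1, t + 1 + span)` — in both cases the
#' `span` bases strictly upstream of the 0-based first transcribed base,
#' clipped at the chromosome start.
#'
#' @param annot `gene_annotation` data frame.
#' @param span window size in bp (> 0; default 5000).
#' @return data.frame of class `promoter_regions`: gene_id, chrom, start,
#'   end (0-based half-open).
#' @examples
#' a <- data.frame(gene_id = "g1", biotype = "lncRNA", chrom = "chr1",
#'                 strand = "+", tss = 10000)
#' promoter_regions(validate_annotation(a))  # [5000, 10000)
#' @export
promoter_regions <- function(annot, span = 5000L) {
  assert_that(span > 0, "span must be > 0")
  annot <- validate_annotation(as.data.frame(annot))
  plus <- annot$strand == "+"
  start <- ifelse(plus, pmax(0L, annot$tss - span), annot$tss + 1L)
  end <- ifelse(plus, annot$tss, annot$tss + 1L + span)
  out <- data.frame(gene_id = annot$gene_id, chrom = annot$chrom,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_regions", "data.frame")
  out
}

#' Assign CpGs to promoter windows with coverage accounting
#'
#' Overlap is computed with GenomicRanges; a CpG maps to every promoter
#' containing it (overlapping promoters share CpGs). Promoters with zero
#' assayed CpGs are excluded from testing but reported in the coverage
#' table. When the total number of promoter CpGs is known (e.g. from a
#' reference CpG catalogue), the covered fraction is reported.
#'
#' @param cpgmap data.frame: cpg_id, chrom, pos (0-based).
#' @param promoters `promoter_regions` data frame.
#' @param total_cpgs optional named vector: true total promoter CpG count
#'   per gene, for covered-fraction reporting.
#' @return List with `assignment` (cpg_id, gene_id) and `coverage`
#'   (gene_id, n_assayed, covered_fraction — NA when totals unknown).
#' @export
assign_cpgs <- function(cpgmap, promoters, total_cpgs = NULL) {
  if (nrow(cpgmap) == 0L || nrow(promoters) == 0L) {
    assignment <- data.frame(cpg_id = character(0), gene_id = character(0),
                             stringsAsFactors = FALSE)
  } else {
    # 0-based half-open -> 1-based closed for IRanges
    cpg_gr <- GenomicRanges::GRanges(
      cpgmap$chrom, IRanges::IRanges(cpgmap$pos + 1L, width = 1L))
    prom_gr <- GenomicRanges::GRanges(
      promoters$chrom, IRanges::IRanges(promoters$start + 1L, promoters$end))
    hits <- GenomicRanges::findOverlaps(cpg_gr, prom_gr)
    assignment <- data.frame(
      cpg_id = cpgmap$cpg_id[S4Vectors::queryHits(hits)],
      gene_id = promoters$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  }
  n_assayed <- table(factor(assignment$gene_id, levels = promoters$gene_id))
  coverage <- data.frame(
    gene_id = promoters$gene_id,
    n_assayed = as.integer(n_assayed),
    covered_fraction = if (is.null(total_cpgs)) NA_real_ else
      as.integer(n_assayed) / as.numeric(total_cpgs[promoters$gene_id]),
    stringsAsFactors = FALSE)
  list(assignment = assignment, coverage = coverage)
}

#' Per-CpG hypermethylation test (tumor vs normal beta-values)
#'
#' For every CpG assigned to at least one promoter, computes
#' `delta_beta = mean(tumor) - mean(normal)` and a one-sided rank test
#' toward hypermethylation: Wilcoxon signed-rank on tumor - normal for
#' paired designs, Mann-Whitney U otherwise. q-values are BH-adjusted
#' across all tested CpGs. CpGs whose beta-values are constant across all
#' samples get p = 1 with a warning.
#'
#' @param beta CpG x sample matrix of beta-values in `[0, 1]`.
#' @param assignment assignment data.frame from [assign_cpgs()] (or any
#'   data frame with a cpg_id column); only these CpGs are tested.
#' @param normal_samples,tumor_samples column ids of the two conditions;
#'   for `paired = TRUE` they must be positionally matched.
#' @param paired use the signed-rank test on matched pairs (default TRUE).
#' @param alternative `"greater"` (hypermethylation, default) or
#'   `"two.sided"`.
#' @return data.frame: cpg_id, delta_beta, statistic, p, q.
#' @export
percpg_hypermethylation_test <- function(beta, assignment, normal_samples,
                                         tumor_samples, paired = TRUE,
                                         alternative = c("greater",
                                                         "two.sided")) {
  alternative <- match.arg(alternative)
  assert_that(all(beta >= 0 & beta <= 1), "beta-values must lie in [0, 1]")
  if (paired)
    assert_that(length(normal_samples) == length(tumor_samples),
                "paired design needs matched sample vectors")
  n_min <- if (paired) 3L else 3L
  assert_that(length(normal_samples) >= n_min && length(tumor_samples) >= n_min,
              "need >= 3 samples (pairs) per condition")
  cpgs <- unique(assignment$cpg_id)
  cpgs <- cpgs[cpgs %in% rownames(beta)]
  bn <- beta[cpgs, normal_samples, drop = FALSE]
  bt <- beta[cpgs, tumor_samples, drop = FALSE]
  dbeta <- rowMeans(bt) - rowMeans(bn)

  res <- vapply(seq_along(cpgs), function(i) {
    x <- bt[i, ]; y <- bn[i, ]
    if (stats::sd(c(x, y)) == 0) {
      warning(sprintf("CpG %s constant across samples; p set to 1", cpgs[i]),
              call. = FALSE)
      return(c(NA_real_, 1))
    }
    if (paired) {
      signed_rank_exact(x - y, alternative)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = alternative))
      p <- wt$p.value
      c(unname(wt$statistic), if (is.finite(p)) p else 1)
    }
  }, numeric(2L))
  data.frame(cpg_id = cpgs, delta_beta = dbeta, statistic = res[1L, ],
             p = res[2L, ], q = bh_adjust(res[2L, ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Exact Wilcoxon signed-rank test by sign-flip enumeration, tie-robust:
# the null distribution of W (sum of |d| midranks over positive d, zeros
# dropped) is built by dynamic-programming convolution over doubled
# midranks, so tied magnitudes — e.g. a constant tumor-normal shift —
# keep an exact p instead of falling back to a normal approximation.
# Used for n <= 30 pairs; beyond that the normal approximation is ample.
signed_rank_exact <- function(d, alternative = "greater", max_exact = 30L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(c(0, 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n > max_exact) {
    wt <- suppressWarnings(
      stats::wilcox.test(d, alternative = alternative, exact = FALSE))
    p <- wt$p.value
    return(c(w, if (is.finite(p)) p else 1))
  }
  r2 <- as.integer(round(2 * r))  # doubled midranks are integers
  counts <- numeric(sum(r2) + 1L)
  counts[1L] <- 1
  for (rr in r2) {
    counts <- counts + c(numeric(rr), counts[seq_len(length(counts) - rr)])
  }
  w2 <- as.integer(round(2 * w))
  tail_ge <- sum(counts[(w2 + 1L):length(counts)]) / 2^n
  tail_le <- sum(counts[seq_len(w2 + 1L)]) / 2^n
  p <- switch(alternative,
              greater = tail_ge,
              less = tail_le,
              two.sided = min(1, 2 * min(tail_ge, tail_le)))
  c(w, p)
}

#' Call hypermethylated promoters from per-CpG results
#'
#' A promoter is flagged hypermethylated when at least one of its
#' assigned CpGs has `q < alpha` and `delta_beta >= delta_min`. The top
#' CpG is the assigned CpG with the smallest q (ties: largest
#' delta_beta, then cpg_id).
#'
#' @param percpg per-CpG results from [percpg_hypermethylation_test()].
#' @param assignment assignment data.frame from [assign_cpgs()].
#' @param alpha BH q-value threshold (default 0.05).
#' @param delta_min minimum delta-beta (default 0.1).
#' @return data.frame of class `promoter_call`: gene_id, n_cpg,
#'   hypermethylated, top_cpg, top_q, top_delta_beta. Promoters with no
#'   assayed CpG are omitted (they cannot be tested).
#' @export
call_hypermethylated_promoters <- function(percpg, assignment, alpha = 0.05,
                                           delta_min = 0.1) {
  merged <- merge(assignment, percpg, by = "cpg_id")
  genes <- sort(unique(merged$gene_id))
  rows <- lapply(genes, function(g) {
    sub <- merged[merged$gene_id == g, ]
    sub <- sub[order(sub$q, -sub$delta_beta, sub$cpg_id), ]
    pass <- sub$q < alpha & sub$delta_beta >= delta_min
    hyper <- any(pass, na.rm = TRUE)
    top <- if (hyper) sub[which(pass)[1L], ] else sub[1L, ]
    data.frame(gene_id = g, n_cpg = nrow(sub), hypermethylated = hyper,
               top_cpg = top$cpg_id, top_q = top$q,
               top_delta_beta = top$delta_beta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_cpg = integer(0),
                      hypermethylated = logical(0), top_cpg = character(0),
                      top_q = numeric(0), top_delta_beta = numeric(0))
  class(out) <- c("promoter_call", "data.frame")
  out
}
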
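# Signature scoring, Spearman correlation, extreme-quantile patient
# stratification, categorical enrichment, and Kaplan-Meier / log-rank
# survival analysis (survival-package engines behind stable surfaces).

#' Mean-expression signature score per sample
#'
#' @param expr genes x samples normalized expression matrix.
#' @param gene_set character vector of gene ids; members absent from the
#'   matrix are dropped with a message, an empty intersection is an error.
#' @return Named numeric vector: per-sample mean over the set's rows.
#' @export
signature_score <- function(expr, gene_set) {
  present <- intersect(gene_set, rownames(expr))
  assert_that(length(present) > 0L,
              "no signature gene present in the expression matrix")
  if (length(present) < length(gene_set))
    message(sprintf("%d of %d signature genes absent from matrix",
                    length(gene_set) - length(present), length(gene_set)))
  colMeans(expr[present, , drop = FALSE])
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses the exact null distribution for n <= 10
#' without ties and the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y paired numeric vectors, n >= 3, no missing values.
#' @return List: rho, p, n, method.
#' @export
spearman_corr <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must be paired")
  n <- length(x)
  assert_that(n >= 3L, "need n >= 3")
  assert_that(!anyNA(x) && !anyNA(y), "missing values not allowed")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Stratify patients into extreme score subgroups
#'
#' The `k` highest-scoring patients form subgroup `#1`, the `k` lowest
#' subgroup `#2`; everyone else is unassigned (NA). Boundary ties are
#' broken deterministically by sample id, with a message.
#'
#' @param scores named numeric vector of signature scores.
#' @param k patients per extreme (default 45); `2k <= n` required.
#' @return Named character vector over all samples: `"#1"`, `"#2"` or NA.
#' @export
stratify_extremes <- function(scores, k = 45L) {
  n <- length(scores)
  assert_that(2L * k <= n, "2k (%d) exceeds the number of patients (%d)",
              2L * k, n)
  assert_that(!is.null(names(scores)), "scores must be named by sample id")
  ord <- order(scores, names(scores))  # ascending; id breaks ties
  ranked <- names(scores)[ord]
  dup_boundary <- anyDuplicated(scores) > 0
  if (dup_boundary)
    message("tied scores present; boundary ties resolved by sample id")
  out <- stats::setNames(rep(NA_character_, n), names(scores))
  out[ranked[seq_len(k)]] <- "#2"            # lowest expression
  out[ranked[seq.int(n - k + 1L, n)]] <- "#1"  # highest expression
  out
}

#' Categorical enrichment test between subgroups
#'
#' Fisher's exact test for 2x2 tables with any expected cell below 5,
#' otherwise the chi-squared test without continuity correction; the
#' method used is reported.
#'
#' @param tab non-negative integer contingency table (r x c).
#' @return List: statistic (NA for Fisher), p, method.
#' @export
categorical_enrichment <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0) && all(tab == round(tab)),
              "table must hold non-negative integers")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "degenerate table: zero margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2L, 2L)) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value, method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chi-squared")
  }
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @return data.frame of class `km_fit`: time, n_risk, n_event, surv —
#'   the right-continuous step function, starting from S(0) = 1.
#' @export
km_estimate <- function(times, events) {
  assert_that(all(times >= 0), "negative survival time")
  assert_that(length(times) == length(events), "times/events length mismatch")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Accumulates observed minus expected events with hypergeometric
#' variance over the distinct event times;
#' `chisq = (O1 - E1)^2 / V` referred to a 1-df chi-squared distribution.
#'
#' @param times,events as in [km_estimate()].
#' @param groups two-level grouping vector, both levels non-empty.
#' @return List: chisq, p, obs (per group), exp (per group).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  assert_that(nlevels(groups) == 2L, "log-rank needs exactly 2 groups")
  assert_that(all(table(groups) > 0), "both groups must be non-empty")
  assert_that(sum(events) > 0, "no events: log-rank p undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Per-gene survival association by expression split
#'
#' For each gene, splits patients by the chosen rule (median split or
#' extreme-k groups) on its expression and runs a log-rank test. Genes
#' whose split is ill-defined (constant expression) are skipped with a
#' warning. p-values are BH-adjusted over tested genes.
#'
#' @param expr genes x samples normalized expression.
#' @param clinical `clinical_table` with sample_id, os_time, os_event;
#'   joined to `expr` by sample id.
#' @param split `"median"` (default) or `"extremes_k"`.
#' @param k extreme-group size when `split = "extremes_k"`.
#' @param alpha significance level for the summary count (default 0.05).
#' @return List: `table` (gene_id, p, q, n_high, n_low) and
#'   `n_significant` at `alpha`.
#' @export
per_gene_survival <- function(expr, clinical, split = c("median", "extremes_k"),
                              k = 45L, alpha = 0.05) {
  split <- match.arg(split)
  common <- intersect(colnames(expr), clinical$sample_id)
  assert_that(length(common) > 0L, "no shared samples between inputs")
  cl <- clinical[match(common, clinical$sample_id), ]
  ex <- expr[, common, drop = FALSE]

  rows <- lapply(rownames(ex), function(g) {
    v <- stats::setNames(ex[g, ], common)
    if (stats::sd(v) == 0) {
      warning(sprintf("gene %s constant; survival split skipped", g),
              call. = FALSE)
      return(NULL)
    }
    if (split == "median") {
      grp <- ifelse(v > stats::median(v), "high", "low")
      if (length(unique(grp)) < 2L) {
        warning(sprintf("gene %s: degenerate median split skipped", g),
                call. = FALSE)
        return(NULL)
      }
      keep <- rep(TRUE, length(v))
    } else {
      sub <- stratify_extremes(v, k = k)
      grp <- ifelse(sub == "#1", "high", "low")
      keep <- !is.na(sub)
    }
    lr <- logrank_test(cl$os_time[keep], cl$os_event[keep], grp[keep])
    data.frame(gene_id = g, p = lr$p, n_high = sum(grp[keep] == "high"),
               n_low = sum(grp[keep] == "low"), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  assert_that(!is.null(tab), "no gene produced a valid survival split")
  tab$q <- bh_adjust(tab$p)
  list(table = tab[, c("gene_id", "p", "q", "n_high", "n_low")],
       n_significant = sum(tab$p < alpha))
}
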
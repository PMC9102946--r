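# Between-sample normalization: library sizes, TMM scaling factors, and
# the log2-CPM transform used by every downstream expression stage.

#' Per-sample library sizes
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(counts) {
  assert_that(is.matrix(counts) && nrow(counts) > 0 && ncol(counts) > 0,
              "counts must be a non-empty matrix")
  assert_that(all(counts >= 0), "counts must be non-negative")
  ls <- colSums(counts)
  zero <- ls == 0
  if (any(zero))
    stop_hepident("sample(s) with all-zero counts cannot be normalized: %s",
                  paste(colnames(counts)[zero], collapse = ", "))
  ls
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Computes, for each sample against a reference sample, the weighted mean
#' of gene-wise log-ratios `M_g = log2((c_gs/L_s)/(c_gr/L_r))` after doubly
#' trimming genes by the M and by the average-abundance
#' `A_g = (log2(c_gs/L_s) + log2(c_gr/L_r))/2` distributions, with inverse
#' asymptotic-variance weights
#' `w_g = 1/((L_s - c_gs)/(L_s c_gs) + (L_r - c_gr)/(L_r c_gr))`.
#' Genes with a zero count in either member of the pair are excluded from
#' factor estimation (the log-ratio is undefined). If no reference is
#' given, the sample whose upper-quartile count fraction is closest to
#' the mean of those fractions is used. Factors are rescaled to have
#' geometric mean 1. Trim fractions of 0 disable trimming.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param ref_sample optional reference sample id or column index.
#' @param trim_M,trim_A two-sided trim fractions for the M and A
#'   distributions (defaults 0.30 / 0.05, the method's canonical values).
#' @param weighted use inverse-variance weights (default TRUE).
#' @return List of class `norm_factors` with `lib_size` and `tmm_factor`
#'   (both named by sample), plus the chosen `ref_sample`.
#' @examples
#' cm <- matrix(rpois(40, 50), 10, 4,
#'              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' tmm_factors(cm)
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_M = 0.30,
                        trim_A = 0.05, weighted = TRUE) {
  assert_that(ncol(counts) >= 2L, "TMM needs at least 2 samples")
  assert_that(trim_M >= 0 && trim_M < 0.5 && trim_A >= 0 && trim_A < 0.5,
              "trim fractions must lie in [0, 0.5)")
  ls <- library_sizes(counts)
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2L, stats::quantile, probs = 0.75) / ls
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    assert_that(!is.na(ref) && ref >= 1 && ref <= ncol(counts),
                "ref_sample not found")
  }
  f <- vapply(seq_len(ncol(counts)), function(s) {
    pair_tmm(counts[, s], counts[, ref], ls[s], ls[ref],
             trim_M, trim_A, weighted,
             pair = paste(colnames(counts)[c(s, ref)], collapse = " vs "))
  }, numeric(1L))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  structure(list(lib_size = ls,
                 tmm_factor = stats::setNames(f, colnames(counts)),
                 ref_sample = colnames(counts)[ref] %||% ref),
            class = "norm_factors")
}

# One sample vs reference; rank-based double trimming, unrescaled factor.
pair_tmm <- function(obs, ref, n_o, n_r, trim_M, trim_A, weighted, pair = "") {
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_M) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_A) + 1; hi_a <- n + 1 - lo_a
  rm <- rank(m); ra <- rank(a)
  keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  if (sum(keep) < 2)
    stop_hepident("fewer than 2 genes survive TMM trimming (%s)", pair)
  f <- if (weighted) sum(m[keep] / v[keep]) / sum(1 / v[keep])
       else mean(m[keep])
  if (is.na(f)) f <- 0
  2^f
}

#' Log2 counts-per-million with a prior count
#'
#' `x_gs = log2((c_gs + prior) / (L_s f_s + 2 prior) * 1e6)` where
#' `L_s f_s` is the TMM-corrected effective library size. Pass
#' `nf = NULL` to use raw library sizes (factors of 1).
#'
#' @param counts genes x samples count matrix.
#' @param nf `norm_factors` from [tmm_factors()], or NULL.
#' @param prior_count positive offset avoiding log of zero (default 0.5).
#' @return Numeric matrix of log2 CPM, same dimnames as `counts`.
#' @export
log_cpm <- function(counts, nf = NULL, prior_count = 0.5) {
  assert_that(prior_count > 0, "prior_count must be > 0")
  ls <- library_sizes(counts)
  f <- if (is.null(nf)) rep(1, ncol(counts)) else {
    assert_that(inherits(nf, "norm_factors"), "nf must be norm_factors")
    as.numeric(nf$tmm_factor[colnames(counts)])
  }
  eff <- ls * f
  sweep_den <- matrix(eff + 2 * prior_count, nrow(counts), ncol(counts),
                      byrow = TRUE)
  log2((counts + prior_count) / sweep_den * 1e6)
}
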
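# Promoter geometry (strand-aware, 0-based half-open, TSS-exclusive),
# CpG assignment against a brute-force overlap scan, and the
# hypermethylation calling rules.

toy_annot <- function(strand, tss, chrom = "chr1") {
  validate_annotation(data.frame(
    gene_id = paste0("g", seq_along(tss)), biotype = "lncRNA",
    chrom = chrom, strand = strand, tss = tss, stringsAsFactors = FALSE))
}

test_that("promoter windows respect strand and the TSS-exclusive boundary", {
  p <- promoter_regions(toy_annot("+", 10000), span = 5000)
  expect_equal(c(p$start, p$end), c(5000, 10000))
  cpgs <- data.frame(cpg_id = c("in", "out"), chrom = "chr1",
                     pos = c(9999, 10000))
  asg <- assign_cpgs(cpgs, p)
  expect_equal(asg$assignment$cpg_id, "in")

  # clipping at the chromosome start
  pc <- promoter_regions(toy_annot("+", 300), span = 5000)
  expect_equal(c(pc$start, pc$end), c(0, 300))

  # minus strand: window covers 10001..15000 — brute-force membership
  pm <- promoter_regions(toy_annot("-", 10000), span = 5000)
  member <- function(pos) pos >= pm$start & pos < pm$end
  expect_false(member(10000))
  expect_true(member(10001))
  expect_true(member(15000))
  expect_false(member(15001))
  expect_equal(sum(vapply(9990:15010, member, logical(1))), 5000)

  bad <- data.frame(gene_id = "g1", biotype = "lncRNA", chrom = "chr1",
                    strand = "*", tss = 100)
  expect_error(promoter_regions(bad), "strand")
  expect_error(promoter_regions(toy_annot("+", 10), span = 0), "span")
})

test_that("CpG assignment equals the O(n*m) brute-force overlap scan", {
  set.seed(6)
  ann <- toy_annot(sample(c("+", "-"), 50, TRUE),
                   sort(sample(10000:200000, 50)),
                   chrom = sample(c("chr1", "chr2"), 50, TRUE))
  prom <- promoter_regions(ann, span = 3000)
  cpgs <- data.frame(cpg_id = sprintf("c%04d", 1:1000),
                     chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                     pos = sample(0:210000, 1000))
  asg <- assign_cpgs(cpgs, prom)
  brute <- do.call(rbind, lapply(seq_len(nrow(cpgs)), function(i) {
    hit <- which(prom$chrom == cpgs$chrom[i] & cpgs$pos[i] >= prom$start &
                   cpgs$pos[i] < prom$end)
    if (length(hit) == 0) return(NULL)
    data.frame(cpg_id = cpgs$cpg_id[i], gene_id = prom$gene_id[hit])
  }))
  key <- function(df) sort(paste(df$cpg_id, df$gene_id))
  expect_equal(key(asg$assignment), key(brute))
  # unassigned CpGs exist and promoters with zero CpGs stay in coverage
  expect_lt(nrow(asg$assignment), nrow(cpgs))
  expect_equal(nrow(asg$coverage), nrow(prom))
  expect_true(any(asg$coverage$n_assayed == 0) ||
                all(asg$coverage$n_assayed > 0))
})

test_that("per-CpG test: identical columns give delta 0 and p 1", {
  set.seed(7)
  b <- matrix(runif(5 * 6, 0.2, 0.4), 5, 6,
              dimnames = list(paste0("c", 1:5),
                              c(paste0("N", 1:3), paste0("T", 1:3))))
  b[, 4:6] <- b[, 1:3]
  asg <- data.frame(cpg_id = rownames(b), gene_id = "g1")
  res <- percpg_hypermethylation_test(b, asg, paste0("N", 1:3),
                                      paste0("T", 1:3), paired = TRUE)
  expect_equal(res$delta_beta, rep(0, 5), ignore_attr = TRUE)
  expect_equal(res$p, rep(1, 5))
})

test_that("signed-rank p matches exact enumeration for 20 clean pairs", {
  set.seed(8)
  base <- runif(20, 0.2, 0.4)
  b <- rbind(c1 = c(base, base + 0.3))
  colnames(b) <- c(paste0("N", 1:20), paste0("T", 1:20))
  asg <- data.frame(cpg_id = "c1", gene_id = "g1")
  res <- percpg_hypermethylation_test(b, asg, paste0("N", 1:20),
                                      paste0("T", 1:20), paired = TRUE)
  # all 20 differences positive (a constant shift, so all |d| tied):
  # W at its maximum 210 and the exact sign-flip tail is 2^-20
  expect_equal(res$p, signed_rank_tail(210, 20))
  expect_equal(res$p, 2^-20, tolerance = 1e-12)

  # tie-free case against base R's exact signed-rank distribution and
  # the convolution oracle
  d <- c(rep(0.25, 15), rep(-0.1, 5)) + seq(0.001, 0.02, length.out = 20)
  b2 <- rbind(c1 = c(base, base + d))
  colnames(b2) <- colnames(b)
  res2 <- percpg_hypermethylation_test(b2, asg, paste0("N", 1:20),
                                       paste0("T", 1:20), paired = TRUE)
  w_obs <- sum(rank(abs(d))[d > 0])
  expect_equal(res2$p, psignrank(w_obs - 1, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res2$p, signed_rank_tail(w_obs, 20), tolerance = 1e-10)
})

test_that("promoter calling needs both significance and effect size", {
  pc <- data.frame(cpg_id = c("c1", "c2", "c3"),
                   delta_beta = c(0.25, 0.3, 0.02),
                   statistic = 1, p = c(0.001, 0.2, 0.001),
                   q = c(0.01, 0.3, 0.01))
  asg <- data.frame(cpg_id = c("c1", "c2", "c3"),
                    gene_id = c("gA", "gB", "gC"))
  calls <- call_hypermethylated_promoters(pc, asg)
  expect_equal(calls$hypermethylated[calls$gene_id == "gA"], TRUE)
  expect_equal(calls$hypermethylated[calls$gene_id == "gB"], FALSE)  # q too big
  expect_equal(calls$hypermethylated[calls$gene_id == "gC"], FALSE)  # delta small
  expect_equal(calls$top_cpg[calls$gene_id == "gA"], "c1")

  # no-effect input calls nothing
  pc0 <- pc; pc0$delta_beta <- 0; pc0$q <- 1
  expect_true(!any(call_hypermethylated_promoters(pc0, asg)$hypermethylated))
})

test_that("calling is monotone in alpha and delta_min", {
  set.seed(9)
  pc <- data.frame(cpg_id = sprintf("c%02d", 1:40),
                   delta_beta = runif(40, -0.1, 0.4), statistic = 1,
                   p = runif(40)^2)
  pc$q <- bh_adjust(pc$p)
  asg <- data.frame(cpg_id = pc$cpg_id,
                    gene_id = rep(sprintf("g%02d", 1:10), each = 4))
  called <- function(alpha, dmin) {
    cl <- call_hypermethylated_promoters(pc, asg, alpha = alpha,
                                         delta_min = dmin)
    cl$gene_id[cl$hypermethylated]
  }
  base <- called(0.2, 0.1)
  expect_true(all(called(0.1, 0.1) %in% base))   # lower alpha: subset
  expect_true(all(called(0.2, 0.2) %in% base))   # higher delta_min: subset
})

test_that("silenced genes show promoter hypermethylation and low expression", {
  # anti-correlation property: enough planted genes for a sign test
  aa <- generate_annotation(150, 60, seed = 25)
  cc <- generate_cohort_counts(aa$annot, n_normal = 12, n_tumor = 40,
                               n_planted_down = 24, n_liver_sig = 40,
                               seed = 25, min_planted_baseline = 0)
  sc <- c(aa, cc)
  mm <- generate_methylation(sc$annot, sc$cpgmap, sc$truth, n_pairs = 30,
                             seed = 1)
  prom <- promoter_regions(sc$annot)
  asg <- assign_cpgs(sc$cpgmap, prom)
  res <- percpg_hypermethylation_test(mm$beta, asg$assignment,
                                      names(mm$pairing), unname(mm$pairing),
                                      paired = TRUE)
  calls <- call_hypermethylated_promoters(res, asg$assignment)
  hyper <- calls$gene_id[calls$hypermethylated]
  expect_true(length(hyper) > 0)
  lc <- log_cpm(sc$counts, tmm_factors(sc$counts))
  d_expr <- rowMeans(lc[hyper, sc$condition == "tumor", drop = FALSE]) -
    rowMeans(lc[hyper, sc$condition == "normal", drop = FALSE])
  expect_lt(binom.test(sum(d_expr < 0), length(d_expr),
                       alternative = "greater")$p.value, 0.01)
})
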
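# Generator contracts: validation, determinism, planted-effect moments,
# and the truth-ledger bookkeeping that downstream recovery tests rely on.

test_that("annotation generator validates inputs and is deterministic", {
  expect_error(generate_annotation(0, 10), "n_coding")
  expect_error(generate_annotation(10, 10, genome_size = 1000), "genome_size")
  a1 <- generate_annotation(50, 10, seed = 7)
  a2 <- generate_annotation(50, 10, seed = 7)
  expect_identical(a1, a2)
  a3 <- generate_annotation(50, 10, seed = 8)
  expect_false(identical(a1$annot$tss, a3$annot$tss))
})

test_that("every gene has an upstream CpG and some CpGs are promoter-free", {
  aa <- generate_annotation(300, 60, seed = 1)
  prom <- promoter_regions(aa$annot, span = 5000)
  # brute-force interval scan over all CpGs
  in_prom <- function(g) {
    any(aa$cpgmap$chrom == prom$chrom[g] &
          aa$cpgmap$pos >= prom$start[g] & aa$cpgmap$pos < prom$end[g])
  }
  expect_true(all(vapply(seq_len(nrow(prom)), in_prom, logical(1))))
  cpg_free <- vapply(seq_len(nrow(aa$cpgmap)), function(i) {
    !any(prom$chrom == aa$cpgmap$chrom[i] &
           aa$cpgmap$pos[i] >= prom$start & aa$cpgmap$pos[i] < prom$end)
  }, logical(1))
  expect_gt(sum(cpg_free), 0)
})

test_that("planted fold changes hit their negative-binomial moments", {
  aa <- generate_annotation(30, 10, seed = 2)
  # null effect: logfc_range [0, 0] gives equal expected means
  cc0 <- generate_cohort_counts(aa$annot, n_normal = 500, n_tumor = 500,
                                n_planted_down = 5, logfc_range = c(0, 0),
                                latent_loading = 0, libsize_log_sd = 0,
                                seed = 3)
  pl <- names(cc0$truth$de_genes)
  ratio0 <- rowMeans(cc0$counts[pl, cc0$condition == "tumor"]) /
    rowMeans(cc0$counts[pl, cc0$condition == "normal"])
  expect_true(all(abs(ratio0 - 1) < 0.15))

  # planted effect: tumor/normal mean ratio within 15% of 2^logFC at n=500
  cc <- generate_cohort_counts(aa$annot, n_normal = 500, n_tumor = 500,
                               n_planted_down = 5,
                               logfc_range = c(-4, -4), latent_loading = 0,
                               libsize_log_sd = 0, seed = 3)
  pl <- names(cc$truth$de_genes)
  ratio <- rowMeans(cc$counts[pl, cc$condition == "tumor"]) /
    rowMeans(cc$counts[pl, cc$condition == "normal"])
  expect_true(all(abs(ratio / 2^-4 - 1) < 0.15))
})

test_that("cohort generator bookkeeping and validation", {
  aa <- generate_annotation(30, 12, seed = 1)
  cc <- generate_cohort_counts(aa$annot, n_normal = 5, n_tumor = 10,
                               n_planted_down = 7, seed = 1,
                               min_planted_baseline = 0)
  expect_length(cc$truth$de_genes, 7)
  expect_true(all(grepl("^LNC_", names(cc$truth$de_genes))))
  expect_true(all(names(cc$truth$de_genes) %in% aa$annot$gene_id))
  expect_error(generate_cohort_counts(aa$annot, n_planted_down = 5,
                                      dispersion = 0, seed = 1),
               "dispersion")
  expect_error(generate_cohort_counts(aa$annot, n_planted_down = 13,
                                      seed = 1), "exceeds")
})

test_that("methylation generator couples planted promoters and stays in [0,1]", {
  aa <- generate_annotation(40, 10, seed = 4)
  cc <- generate_cohort_counts(aa$annot, n_normal = 5, n_tumor = 10,
                               n_planted_down = 6, seed = 4,
                               min_planted_baseline = 0)
  mm <- generate_methylation(aa$annot, aa$cpgmap, cc$truth, n_pairs = 200,
                             delta_beta_range = c(0.3, 0.3), seed = 4)
  expect_true(all(mm$beta >= 0 & mm$beta <= 1))
  expect_length(mm$truth$hyperm_promoters, 3)  # ceiling(6 * 0.5)

  # Monte-Carlo moment check at n_pairs = 200: mean delta within 0.05
  prom <- promoter_regions(aa$annot[aa$annot$gene_id %in%
                                      names(mm$truth$hyperm_promoters), ])
  asg <- assign_cpgs(aa$cpgmap, prom)
  normal <- names(mm$pairing); tumor <- unname(mm$pairing)
  cpg <- unique(asg$assignment$cpg_id)
  d <- rowMeans(mm$beta[cpg, tumor]) - rowMeans(mm$beta[cpg, normal])
  expect_true(all(abs(d - 0.3) < 0.05))

  # null coupling: no expected difference
  mm0 <- generate_methylation(aa$annot, aa$cpgmap, cc$truth, n_pairs = 200,
                              delta_beta_range = c(0, 0), seed = 4)
  d0 <- rowMeans(mm0$beta[cpg, unname(mm0$pairing)]) -
    rowMeans(mm0$beta[cpg, names(mm0$pairing)])
  expect_true(all(abs(d0) < 0.05))
  expect_error(generate_methylation(aa$annot, aa$cpgmap, cc$truth,
                                    base_beta = 0.9,
                                    delta_beta_range = c(0.2, 0.4)),
               "within")
})

test_that("tissue panel plants liver preference and fetal reduction", {
  aa <- generate_annotation(40, 10, seed = 5)
  cc <- generate_cohort_counts(aa$annot, n_normal = 5, n_tumor = 10,
                               n_planted_down = 8, seed = 5,
                               min_planted_baseline = 0)
  tt <- generate_tissue_panel(aa$annot, cc$truth, n_reps = 50, seed = 5)
  mu <- tissue_means(tt$expr, tt$tissue_labels)
  pref <- tt$truth$liver_pref_genes
  expect_length(pref, 4)  # floor(8 * 0.5)
  others <- setdiff(colnames(mu), c("liver", "fetal_liver"))
  # planted ratio holds within sampling error at 50 replicates
  obs_ratio <- mu[pref, "liver"] / apply(mu[pref, others], 1, max)
  expect_true(all(obs_ratio > 8 * 0.6))
  expect_true(all(mu[pref, "fetal_liver"] / mu[pref, "liver"] < 1))
  expect_error(generate_tissue_panel(aa$annot, cc$truth, tissues = "liver"),
               "2 tissues")
})

test_that("clinical generator couples survival to score with exponential medians", {
  scores <- setNames(rnorm(374), sprintf("T%03d", 1:374))
  cl0 <- generate_clinical(scores, censor_rate = 0, seed = 6)
  expect_true(all(cl0$os_event == 1))
  expect_error(generate_clinical(scores, censor_rate = 1), "censor_rate")

  # gamma = -0.7: high-score patients live longer (exponential medians)
  cl <- generate_clinical(scores, gamma = -0.7, censor_rate = 0, seed = 6)
  hi <- cl$score >= quantile(cl$score, 0.75)
  lo <- cl$score <= quantile(cl$score, 0.25)
  expect_gt(median(cl$os_time[hi]), median(cl$os_time[lo]))

  # censoring fraction close to its calibrated target
  cl3 <- generate_clinical(setNames(rnorm(2000), paste0("s", 1:2000)),
                           gamma = 0, censor_rate = 0.3, seed = 7)
  expect_lt(abs(mean(1 - cl3$os_event) - 0.3), 0.05)
})

test_that("fixture files are byte-identical for identical seeds", {
  d1 <- file.path(tempdir(), "synthA"); d2 <- file.path(tempdir(), "synthB")
  p <- list(annotation = list(n_coding = 60, n_lnc = 20),
            counts = list(n_normal = 6, n_tumor = 12, n_planted_down = 4,
                          n_liver_sig = 20, min_planted_baseline = 0),
            methylation = list(n_pairs = 6),
            tissue = list(n_reps = 3),
            clinical = list())
  write_synthetic_cohort(d1, seed = 11, params = p)
  write_synthetic_cohort(d2, seed = 11, params = p)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("truth ledger round-trips through JSON without loss", {
  aa <- generate_annotation(20, 8, seed = 9)
  cc <- generate_cohort_counts(aa$annot, n_normal = 4, n_tumor = 8,
                               n_planted_down = 3, seed = 9,
                               min_planted_baseline = 0)
  path <- tempfile(fileext = ".json")
  write_truth(cc$truth, path)
  back <- read_truth(path)
  expect_equal(back$de_genes, unlist(cc$truth$de_genes))
  expect_equal(back$liver_sig_genes, cc$truth$liver_sig_genes)
  expect_equal(back$seed, cc$truth$seed)
})
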
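# Synthetic-cohort generator: annotation + CpG map, negative-binomial
# tumor/normal counts with planted downregulation, beta-value methylation
# coupled to planted silencing, a multi-tissue expression panel, and a
# clinical table whose survival is coupled to a signature score. Every
# planted effect is recorded in a truth ledger so downstream recovery can
# be scored exactly.

#' Generate gene annotation and a CpG map
#'
#' Places `n_coding` protein-coding and `n_lnc` lncRNA genes uniformly on
#' two synthetic chromosomes, assigns each a strand and a TSS (0-based
#' first transcribed base), and scatters CpG sites so that every gene has
#' at least one CpG in the 5,000 bp strictly upstream of its TSS
#' (strand-aware) while a background of CpGs falls outside all promoters —
#' mirroring the sparse promoter coverage of methylation arrays.
#'
#' @param n_coding,n_lnc number of coding / lncRNA genes (both >= 1).
#' @param genome_size chromosome length in bp (default 5e7); must leave
#'   room for non-degenerate TSS placement.
#' @param seed integer seed; identical seeds give identical output.
#' @param span promoter span in bp used to guarantee upstream CpG
#'   coverage (default 5000).
#' @param cpg_per_promoter mean number of extra CpGs per promoter beyond
#'   the guaranteed one (Poisson).
#' @param n_background_cpg number of CpGs placed uniformly at random,
#'   irrespective of promoters.
#' @return List with `annot` (a `gene_annotation` data frame: gene_id,
#'   biotype, chrom, strand, tss) and `cpgmap` (cpg_id, chrom, pos).
#' @examples
#' aa <- generate_annotation(20, 5, seed = 1)
#' table(aa$annot$biotype)
#' @export
generate_annotation <- function(n_coding, n_lnc, genome_size = 5e7,
                                seed = 1L, span = 5000L,
                                cpg_per_promoter = 2, n_background_cpg = 200L) {
  assert_that(n_coding >= 1 && n_lnc >= 1,
              "n_coding and n_lnc must both be >= 1")
  assert_that(genome_size > 4 * span,
              "genome_size too small for non-degenerate TSS placement")
  set.seed(child_seed(seed, "annotation"))
  n <- n_coding + n_lnc
  gene_id <- c(sprintf("CODING_%05d", seq_len(n_coding)),
               sprintf("LNC_%05d", seq_len(n_lnc)))
  annot <- data.frame(
    gene_id = gene_id,
    biotype = rep(c("coding", "lncRNA"), c(n_coding, n_lnc)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tss = as.integer(floor(stats::runif(n, span + 1000, genome_size - span - 1000))),
    stringsAsFactors = FALSE
  )
  annot <- validate_annotation(annot)

  # one guaranteed CpG per promoter + Poisson extras, then uniform background
  prom <- promoter_regions(annot, span = span)
  n_extra <- stats::rpois(n, cpg_per_promoter)
  pos <- integer(0); chrom <- character(0)
  for (i in seq_len(n)) {
    k <- 1L + n_extra[i]
    p <- as.integer(floor(stats::runif(k, prom$start[i], prom$end[i])))
    pos <- c(pos, p)
    chrom <- c(chrom, rep(prom$chrom[i], k))
  }
  bg <- as.integer(floor(stats::runif(n_background_cpg, 0, genome_size)))
  pos <- c(pos, bg)
  chrom <- c(chrom, sample(c("chr1", "chr2"), n_background_cpg, replace = TRUE))
  cpgmap <- data.frame(
    cpg_id = sprintf("cg%07d", seq_along(pos)),
    chrom = chrom, pos = pos, stringsAsFactors = FALSE
  )
  list(annot = annot, cpgmap = cpgmap)
}

#' Generate a tumor/normal RNA-seq count cohort with planted downregulation
#'
#' Draws negative-binomial counts with log-normal gene-wise baseline means
#' and a common dispersion. A chosen number of lncRNAs is planted as
#' downregulated in tumors: their tumor mean equals the normal mean times
#' `2^logFC` with logFC drawn from `logfc_range`. Tumor samples carry a
#' latent differentiation factor `z ~ N(0,1)`: the planted lncRNAs and a
#' designated set of coding "liver-signature" genes are co-regulated
#' through it (mean multiplied by `2^(latent_loading * z)`), emulating the
#' joint loss of liver identity that couples lncRNA silencing, signature
#' expression, tumor grade and survival in real cohorts. Per-sample
#' library-size factors vary log-normally.
#'
#' @param annot gene annotation from [generate_annotation()].
#' @param n_normal,n_tumor samples per arm.
#' @param n_planted_down number of lncRNAs to downregulate (<= number of
#'   lncRNAs in `annot`).
#' @param logfc_range length-2 numeric, planted log2 fold-change interval
#'   (default `c(-6, -3.5)`, tumor vs normal).
#' @param dispersion common negative-binomial dispersion (> 0; default 0.2,
#'   bulk-RNA-seq-like overdispersion).
#' @param seed integer seed.
#' @param latent_loading log2 expression change per SD of the latent
#'   factor for co-regulated genes (default 0.5).
#' @param n_liver_sig number of coding genes designated as the
#'   liver-identity signature (default 249).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   gene-wise baseline means.
#' @param libsize_log_sd SD of log-normal per-sample depth factors.
#' @param min_planted_baseline minimum baseline mean count for a lncRNA
#'   to be eligible for planting (default 100). A strong fold drop
#'   planted on a near-silent gene is unobservable — the gene must be
#'   clearly quantifiable in the normal arm for a log2FC below -3.5 to
#'   exist on the measurement scale, matching the well-expressed
#'   normal-liver profile of the genes such a screen can return.
#' @return List with `counts` (integer matrix, genes x samples),
#'   `condition` (named vector, "normal"/"tumor") and `truth` (a
#'   `truth_ledger`: de_genes with planted logFC, liver_sig_genes, the
#'   latent factor per tumor sample, seed).
#' @export
generate_cohort_counts <- function(annot, n_normal = 50L, n_tumor = 374L,
                                   n_planted_down = 35L,
                                   logfc_range = c(-6, -3.5),
                                   dispersion = 0.2, seed = 1L,
                                   latent_loading = 0.5,
                                   n_liver_sig = 249L,
                                   baseline_meanlog = log(150),
                                   baseline_sdlog = 1.2,
                                   libsize_log_sd = 0.2,
                                   min_planted_baseline = 100) {
  lnc <- annot$gene_id[annot$biotype == "lncRNA"]
  coding <- annot$gene_id[annot$biotype == "coding"]
  assert_that(n_planted_down <= length(lnc),
              "n_planted_down (%d) exceeds the number of lncRNAs (%d)",
              n_planted_down, length(lnc))
  assert_that(dispersion > 0, "dispersion must be > 0")
  assert_that(length(logfc_range) == 2L && all(logfc_range <= 0),
              "logfc_range must be a non-positive interval (downregulation)")
  set.seed(child_seed(seed, "counts"))

  genes <- annot$gene_id
  ng <- length(genes)
  base_mu <- stats::setNames(
    stats::rlnorm(ng, baseline_meanlog, baseline_sdlog), genes)
  plantable <- lnc[base_mu[lnc] >= min_planted_baseline]
  assert_that(length(plantable) >= n_planted_down,
              "only %d lncRNAs reach min_planted_baseline; need %d",
              length(plantable), n_planted_down)
  planted <- sort(sample(plantable, n_planted_down))
  logfc <- stats::setNames(
    stats::runif(n_planted_down, min(logfc_range), max(logfc_range)), planted)
  liver_sig <- sort(sample(coding, min(n_liver_sig, length(coding))))
  sample_id <- c(sprintf("N%03d", seq_len(n_normal)),
                 sprintf("T%03d", seq_len(n_tumor)))
  condition <- stats::setNames(
    rep(c("normal", "tumor"), c(n_normal, n_tumor)), sample_id)
  depth <- stats::rlnorm(n_normal + n_tumor, 0, libsize_log_sd)
  z <- stats::rnorm(n_tumor)  # latent differentiation factor, tumors only

  # per-gene x per-sample mean: baseline x planted FC x latent coupling x depth
  mu <- matrix(base_mu, ng, n_normal + n_tumor)
  tum <- (n_normal + 1L):(n_normal + n_tumor)
  mu[match(planted, genes), tum] <-
    mu[match(planted, genes), tum] * 2^(logfc[planted])
  co <- match(c(planted, liver_sig), genes)
  mu[co, tum] <- mu[co, tum] * rep(2^(latent_loading * z), each = length(co))
  mu <- sweep(mu, 2L, depth, `*`)

  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   ng, ncol(mu), dimnames = list(genes, sample_id))
  truth <- structure(list(
    de_genes = as.list(logfc),
    hyperm_promoters = list(),
    liver_pref_genes = character(0),
    liver_sig_genes = liver_sig,
    latent = stats::setNames(as.list(z), sample_id[tum]),
    hazard_coeff = NA_real_,
    seed = as.integer(seed)
  ), class = "truth_ledger")
  list(counts = counts, condition = condition, truth = truth)
}

#' Generate paired tumor/normal promoter methylation beta-values
#'
#' Draws CpG beta-values from a beta distribution parameterised by mean
#' and precision (clipped to `[0, 1]` by construction). For a subset of
#' the planted downregulated lncRNAs, all promoter CpGs have their tumor
#' mean shifted upward by a planted delta-beta, emulating promoter
#' hypermethylation of silenced genes; all other CpGs share tumor and
#' normal means. Samples are emitted as `n_pairs` matched normal/tumor
#' columns.
#'
#' @param annot,cpgmap from [generate_annotation()].
#' @param truth truth ledger from [generate_cohort_counts()]; updated with
#'   the planted hypermethylated promoters and returned.
#' @param n_pairs matched patient pairs (default 50).
#' @param base_beta baseline CpG methylation mean (default 0.2).
#' @param delta_beta_range planted tumor-normal delta-beta interval
#'   (default `c(0.2, 0.4)`); `base_beta + max` must stay in `[0, 1]`.
#' @param precision beta-distribution precision (mean*precision,
#'   (1-mean)*precision shape parameters; default 30, array-like spread).
#' @param frac_hyperm fraction of planted-DE lncRNAs given promoter
#'   hypermethylation (default 0.5, rounded up).
#' @param span promoter span in bp (default 5000).
#' @param seed integer seed.
#' @return List with `beta` (CpG x sample matrix), `pairing` (named
#'   vector: tumor column per normal column), and updated `truth` whose
#'   `hyperm_promoters` maps gene id to planted delta-beta.
#' @export
generate_methylation <- function(annot, cpgmap, truth, n_pairs = 50L,
                                 base_beta = 0.2,
                                 delta_beta_range = c(0.2, 0.4),
                                 precision = 30, frac_hyperm = 0.5,
                                 span = 5000L, seed = 1L) {
  assert_that(base_beta >= 0 && base_beta + max(delta_beta_range) <= 1,
              "base_beta + max(delta_beta_range) must stay within [0, 1]")
  assert_that(all(delta_beta_range >= 0) && all(delta_beta_range <= 1),
              "delta_beta_range must lie in [0, 1]")
  assert_that(precision > 0, "precision must be > 0")
  set.seed(child_seed(seed, "methylation"))

  de <- names(truth$de_genes)
  n_hyp <- ceiling(length(de) * frac_hyperm)
  hyp_genes <- if (n_hyp > 0) sort(sample(de, n_hyp)) else character(0)
  dbeta <- stats::setNames(
    stats::runif(n_hyp, min(delta_beta_range), max(delta_beta_range)),
    hyp_genes)

  prom <- promoter_regions(annot[annot$gene_id %in% hyp_genes, , drop = FALSE],
                           span = span)
  asg <- assign_cpgs(cpgmap, prom)
  shift <- stats::setNames(rep(0, nrow(cpgmap)), cpgmap$cpg_id)
  if (nrow(asg$assignment) > 0) {
    per_cpg <- tapply(dbeta[asg$assignment$gene_id], asg$assignment$cpg_id, max)
    shift[names(per_cpg)] <- per_cpg
  }

  sample_id <- c(sprintf("P%03d_N", seq_len(n_pairs)),
                 sprintf("P%03d_T", seq_len(n_pairs)))
  mean_n <- rep(base_beta, nrow(cpgmap))
  mean_t <- pmin(mean_n + shift, 1 - 1e-6)
  draw <- function(m) {
    matrix(stats::rbeta(nrow(cpgmap) * n_pairs, m * precision,
                        (1 - m) * precision),
           nrow(cpgmap), n_pairs)
  }
  beta <- cbind(draw(mean_n), draw(mean_t))
  dimnames(beta) <- list(cpgmap$cpg_id, sample_id)
  truth$hyperm_promoters <- as.list(dbeta)
  pairing <- stats::setNames(sample_id[n_pairs + seq_len(n_pairs)],
                             sample_id[seq_len(n_pairs)])
  list(beta = beta, pairing = pairing, truth = truth)
}

#' Generate a multi-tissue expression panel with planted liver preference
#'
#' Emits a CPM-scale expression matrix over replicate samples of 12
#' organs plus fetal-liver columns. Half of the planted downregulated
#' lncRNAs (by default) are planted as liver-preferential: their adult
#' liver mean exceeds every other organ's mean by the factor `ratio`, and
#' their fetal-liver mean is reduced `fetal_reduction`-fold relative to
#' adult liver. All remaining genes are expressed at a common level in
#' every tissue (ubiquitous). Noise is log-normal around tissue means.
#'
#' @param annot gene annotation.
#' @param truth truth ledger; updated with `liver_pref_genes`.
#' @param tissues character vector of organ names, must contain
#'   `"liver"`, length >= 2 (default: 12 organs).
#' @param n_reps replicate samples per tissue (default 20).
#' @param ratio planted liver/other mean expression ratio (> 1; default 8).
#' @param fetal_reduction planted adult/fetal mean ratio for
#'   liver-preferential genes (default 8).
#' @param frac_liver_pref fraction of planted-DE lncRNAs made
#'   liver-preferential (default 0.5).
#' @param noise_sdlog log-normal noise SD (default 0.4).
#' @param seed integer seed.
#' @return List with `expr` (gene x sample CPM-scale matrix),
#'   `tissue_labels` (named vector incl. `"fetal_liver"`), updated `truth`.
#' @export
generate_tissue_panel <- function(annot, truth,
                                  tissues = c("liver", "lung", "breast",
                                              "kidney", "prostate", "stomach",
                                              "uterus", "thyroid", "colon",
                                              "head_neck", "pancreas",
                                              "bladder"),
                                  n_reps = 20L, ratio = 8, fetal_reduction = 8,
                                  frac_liver_pref = 0.5, noise_sdlog = 0.4,
                                  seed = 1L) {
  assert_that(length(tissues) >= 2L, "need at least 2 tissues")
  assert_that("liver" %in% tissues, "tissues must include 'liver'")
  assert_that(ratio >= 1, "ratio must be >= 1")
  set.seed(child_seed(seed, "tissue_panel"))

  de <- names(truth$de_genes)
  n_pref <- floor(length(de) * frac_liver_pref)
  pref <- if (n_pref > 0) sort(sample(de, n_pref)) else character(0)

  genes <- annot$gene_id
  all_t <- c(tissues, "fetal_liver")
  sample_id <- unlist(lapply(all_t, function(t)
    sprintf("%s_%02d", t, seq_len(n_reps))))
  tissue_labels <- stats::setNames(rep(all_t, each = n_reps), sample_id)

  base <- stats::setNames(stats::rlnorm(length(genes), log(50), 0.8), genes)
  mu <- matrix(base, length(genes), length(sample_id),
               dimnames = list(genes, sample_id))
  is_pref <- genes %in% pref
  non_liver <- !(tissue_labels %in% c("liver", "fetal_liver"))
  mu[is_pref, non_liver] <- mu[is_pref, non_liver] / ratio
  mu[is_pref, tissue_labels == "fetal_liver"] <-
    mu[is_pref, tissue_labels == "fetal_liver"] / fetal_reduction
  expr <- mu * stats::rlnorm(length(mu), 0, noise_sdlog)
  truth$liver_pref_genes <- pref
  list(expr = expr, tissue_labels = tissue_labels, truth = truth)
}

#' Generate a clinical table with survival coupled to a signature score
#'
#' Survival times are exponential with hazard `h0 * exp(gamma * z)`,
#' where `z` is the standardized signature score, so `gamma < 0` makes
#' high-score patients live longer. Censoring is independent and uniform
#' on `[0, q]` with `q` calibrated so the expected censoring fraction is
#' `censor_rate`. Histological grade (G1-G4) and pathological stage
#' (T1-T4) are drawn from ordered-logit models whose latent scale is
#' monotone in `-z`: low-score (de-differentiated) patients skew toward
#' high grade and stage.
#'
#' @param expr_scores named numeric vector, one signature score per
#'   sample (names = sample ids).
#' @param gamma log-hazard per SD of score (default -0.7).
#' @param censor_rate expected fraction censored, in `[0, 1)` (default 0.3).
#' @param grade_probs,stage_probs baseline marginal distributions over
#'   G1-G4 / T1-T4.
#' @param grade_coef latent-scale coupling of grade and stage to `-z`
#'   (default 0.8).
#' @param h0 baseline hazard per day (default `log(2)/730`: two-year
#'   median survival at score 0).
#' @param seed integer seed.
#' @return A `data.frame` (class `clinical_table`): sample_id, os_time
#'   (days), os_event (0/1), grade, stage, score.
#' @export
generate_clinical <- function(expr_scores, gamma = -0.7, censor_rate = 0.3,
                              grade_probs = c(0.25, 0.4, 0.25, 0.1),
                              stage_probs = c(0.5, 0.25, 0.15, 0.1),
                              grade_coef = 0.8, h0 = log(2) / 730,
                              seed = 1L) {
  assert_that(censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  assert_that(!is.null(names(expr_scores)), "expr_scores must be named")
  set.seed(child_seed(seed, "clinical"))
  n <- length(expr_scores)
  z <- as.numeric(scale(expr_scores))
  haz <- h0 * exp(gamma * z)
  t_event <- stats::rexp(n, rate = haz)

  if (censor_rate == 0) {
    os_time <- t_event
    os_event <- rep(1L, n)
  } else {
    # q solving (1 - exp(-h0 q)) / (h0 q) = censor_rate for uniform C on [0,q]
    f <- function(q) (1 - exp(-h0 * q)) / (h0 * q) - censor_rate
    q <- stats::uniroot(f, c(1e-6, 1e9))$root
    cens <- stats::runif(n, 0, q)
    os_event <- as.integer(t_event <= cens)
    os_time <- pmin(t_event, cens)
  }

  ordered_draw <- function(probs, prefix) {
    cuts <- stats::qlogis(cumsum(probs)[-length(probs)])
    u <- -grade_coef * z + stats::rlogis(n)
    idx <- 1L + rowSums(outer(u, cuts, `>`))
    factor(paste0(prefix, idx), levels = paste0(prefix, seq_along(probs)))
  }
  out <- data.frame(
    sample_id = names(expr_scores),
    os_time = os_time,
    os_event = os_event,
    grade = ordered_draw(grade_probs, "G"),
    stage = ordered_draw(stage_probs, "T"),
    score = as.numeric(expr_scores),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write a complete synthetic cohort to a directory
#'
#' Runs all generators under one master seed and writes the plain-text
#' fixture set: counts.tsv, conditions.tsv, beta.tsv, pairing.tsv,
#' cpg.bed, genes.bed, gene_info.tsv, tissue_panel.tsv, tissues.tsv,
#' clinical.tsv and truth.json. Identical seeds and parameters produce
#' byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param params named list overriding generator defaults; recognised
#'   blocks: `annotation`, `counts`, `methylation`, `tissue`, `clinical`,
#'   each a list of arguments for the matching generator.
#' @return Invisibly, the list of generated objects (incl. `truth`).
#' @export
write_synthetic_cohort <- function(out_dir, seed = 1L, params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aa <- do.call(generate_annotation,
                c(list(seed = seed), params$annotation %||%
                    list(n_coding = 1500L, n_lnc = 500L)))
  cc <- do.call(generate_cohort_counts,
                c(list(annot = aa$annot, seed = seed), params$counts))
  mm <- do.call(generate_methylation,
                c(list(annot = aa$annot, cpgmap = aa$cpgmap, truth = cc$truth,
                       seed = seed), params$methylation))
  tt <- do.call(generate_tissue_panel,
                c(list(annot = aa$annot, truth = mm$truth, seed = seed),
                  params$tissue))
  # the clinical score is the mean log-CPM of the planted genes in tumors
  nf <- tmm_factors(cc$counts)
  lc <- log_cpm(cc$counts, nf)
  tumor <- names(cc$condition)[cc$condition == "tumor"]
  sc <- signature_score(lc[, tumor, drop = FALSE], names(cc$truth$de_genes))
  cl <- do.call(generate_clinical,
                c(list(expr_scores = sc, seed = seed), params$clinical))
  truth <- tt$truth
  truth$hazard_coeff <- params$clinical$gamma %||% eval(formals(generate_clinical)$gamma)

  write_matrix_tsv(cc$counts, file.path(out_dir, "counts.tsv"), "gene_id")
  write_labels_tsv(cc$condition, file.path(out_dir, "conditions.tsv"))
  write_matrix_tsv(mm$beta, file.path(out_dir, "beta.tsv"), "cpg_id")
  write_labels_tsv(mm$pairing, file.path(out_dir, "pairing.tsv"), "tumor_sample")
  write_cpg_bed(aa$cpgmap, file.path(out_dir, "cpg.bed"))
  write_genes_bed(aa$annot, file.path(out_dir, "genes.bed"))
  write_gene_info(aa$annot, file.path(out_dir, "gene_info.tsv"))
  write_matrix_tsv(tt$expr, file.path(out_dir, "tissue_panel.tsv"), "gene_id")
  write_labels_tsv(tt$tissue_labels, file.path(out_dir, "tissues.tsv"), "tissue")
  utils::write.table(cl, file.path(out_dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth(truth, file.path(out_dir, "truth.json"))
  invisible(list(annot = aa$annot, cpgmap = aa$cpgmap, counts = cc$counts,
                 condition = cc$condition, beta = mm$beta,
                 pairing = mm$pairing, tissue = tt, clinical = cl,
                 truth = truth))
}
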
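# End-to-end orchestration: synthesize-or-load inputs, normalize,
# consensus DE, top-set selection, promoter methylation, tissue
# classification, clinical outcomes and guilt-by-association, under one
# config with a machine-readable run report.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "hepident_run",
    synthesize = TRUE,
    synth = list(),        # per-generator overrides, see write_synthetic_cohort
    inputs = list(),       # file paths when synthesize = FALSE
    consensus = list(n_tumor_draw = 50L, R = 200L, fdr_threshold = 0.01,
                     direction = "down"),
    top = list(logfc_cut = -3.5, fdr_cut = 0.05, n_top = 35L),
    methylation = list(span = 5000L, alpha = 0.05, delta_min = 0.1,
                       paired = TRUE),
    tissue = list(expr_floor = 1, similarity_ratio = 0.5, k = 3L),
    clinical = list(k = 45L),
    gba = list(p_w = 1, n_perm = 1000L, n_targets = 1L),
    prior_count = 0.5
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unspecified values fall back
#' to the pipeline defaults, which equal the published analysis
#' parameters wherever one exists (R = 200 iterations, 50-tumor draws,
#' FDR < 1% consensus, logFC < -3.5 & FDR < 0.05 top set of 35, 5,000 bp
#' promoter span, 45-patient extreme subgroups, quartile GBA split).
#'
#' @param config NULL (defaults), a YAML path, or a named list.
#' @return Fully merged config list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or YAML path")
  merge_config(base, config)
}

load_inputs <- function(cfg) {
  ins <- cfg$inputs
  need <- function(nm) {
    assert_that(!is.null(ins[[nm]]) && file.exists(ins[[nm]]),
                "required input '%s' missing or not found", nm)
    ins[[nm]]
  }
  counts <- read_matrix_tsv(need("counts"))
  condition <- read_labels_tsv(need("conditions"))
  annot <- read_gene_info(need("gene_info"))
  out <- list(counts = counts, condition = condition, annot = annot)
  if (!is.null(ins$beta)) {
    out$beta <- read_matrix_tsv(ins$beta)
    out$cpgmap <- read_cpg_bed(need("cpg_bed"))
    if (!is.null(ins$pairing)) out$pairing <- read_labels_tsv(ins$pairing)
  }
  if (!is.null(ins$tissue_panel)) {
    out$tissue <- list(expr = read_matrix_tsv(ins$tissue_panel),
                       tissue_labels = read_labels_tsv(need("tissues")))
  }
  if (!is.null(ins$clinical)) {
    cl <- utils::read.delim(ins$clinical, stringsAsFactors = FALSE)
    class(cl) <- c("clinical_table", "data.frame")
    out$clinical <- cl
  }
  if (!is.null(ins$truth)) out$truth <- read_truth(ins$truth)
  if (!is.null(ins$gene_sets)) out$gene_sets <- read_gmt(ins$gene_sets)
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input synthesis (or loading),
#' TMM + log-CPM normalization, subsampling-consensus differential
#' expression, top-set selection, promoter-methylation calling, tissue
#' classification with the fetal-adult contrast, clinical outcomes
#' (signature scores, liver-signature correlation, extreme-k
#' stratification, grade/stage enrichment, Kaplan-Meier + log-rank,
#' per-gene survival), and guilt-by-association enrichment for the top
#' target(s). Stages whose inputs are absent are skipped and noted in
#' the report. All tabular outputs are written as TSV under
#' `cfg$out_dir`.
#'
#' @param config as accepted by [load_config()].
#' @return A run report (list): resolved parameters, per-stage timings,
#'   notes and output paths, input md5 hashes, and the key result
#'   objects under `$results`. The report (minus `$results`) is also
#'   written as `run_report.json`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, parameters = cfg[setdiff(names(cfg),
                   c("inputs", "out_dir"))], stages = list())
  results <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    report$stages[[name]] <<- c(report$stages[[name]],
                                list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)))
    val
  }
  note <- function(name, msg) {
    report$stages[[name]] <<- c(report$stages[[name]], list(note = msg))
  }

  # --- inputs -------------------------------------------------------------
  dat <- timed("inputs", {
    if (isTRUE(cfg$synthesize)) {
      synth_dir <- file.path(cfg$out_dir, "synthetic")
      obj <- write_synthetic_cohort(synth_dir, seed = cfg$seed,
                                    params = cfg$synth)
      obj$tissue <- list(expr = obj$tissue$expr,
                         tissue_labels = obj$tissue$tissue_labels)
      obj
    } else load_inputs(cfg)
  })
  in_files <- if (isTRUE(cfg$synthesize))
    list.files(file.path(cfg$out_dir, "synthetic"), full.names = TRUE)
  else unlist(cfg$inputs)
  report$input_md5 <- as.list(tools::md5sum(in_files[file.exists(in_files)]))

  # --- normalization ------------------------------------------------------
  lc <- timed("normalize", {
    nf <- tmm_factors(dat$counts)
    results$norm_factors <- nf
    lc <- log_cpm(dat$counts, nf, prior_count = cfg$prior_count)
    write_matrix_tsv(lc, file.path(cfg$out_dir, "logcpm.tsv"), "gene_id")
    utils::write.table(
      data.frame(sample_id = names(nf$lib_size), lib_size = nf$lib_size,
                 tmm_factor = nf$tmm_factor),
      file.path(cfg$out_dir, "factors.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    lc
  })

  # --- consensus DE + top set --------------------------------------------
  top <- timed("consensus", {
    cr <- do.call(subsample_consensus,
                  c(list(counts = dat$counts, condition = dat$condition,
                         seed = cfg$seed, prior_count = cfg$prior_count),
                    cfg$consensus))
    grp <- factor(dat$condition[colnames(lc)], levels = c("normal", "tumor"))
    de <- moderated_t(lc, grp)
    out <- merge(as.data.frame(cr), as.data.frame(de)[, c("gene_id", "logfc",
                                                          "p", "q")],
                 by = "gene_id")
    utils::write.table(out[order(out$logfc), ],
                       file.path(cfg$out_dir, "consensus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    top <- do.call(select_top, c(list(cr = cr, de = de), cfg$top))
    writeLines(top, file.path(cfg$out_dir, "top_genes.txt"))
    results$consensus <- cr; results$de_full <- de; results$top_genes <- top
    top
  })

  # --- promoter methylation ----------------------------------------------
  if (!is.null(dat$beta)) {
    timed("methylation", {
      prom <- promoter_regions(dat$annot[dat$annot$gene_id %in% top, ,
                                         drop = FALSE],
                               span = cfg$methylation$span)
      asg <- assign_cpgs(dat$cpgmap, prom)
      paired <- isTRUE(cfg$methylation$paired) && !is.null(dat$pairing)
      if (paired) {
        norm_s <- names(dat$pairing); tum_s <- unname(dat$pairing)
      } else {
        # fall back: columns named *_N / *_T
        norm_s <- grep("_N$", colnames(dat$beta), value = TRUE)
        tum_s <- grep("_T$", colnames(dat$beta), value = TRUE)
      }
      pc <- percpg_hypermethylation_test(dat$beta, asg$assignment,
                                         norm_s, tum_s, paired = paired)
      calls <- call_hypermethylated_promoters(pc, asg$assignment,
                                              alpha = cfg$methylation$alpha,
                                              delta_min = cfg$methylation$delta_min)
      utils::write.table(calls, file.path(cfg$out_dir, "promoter_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$promoter_calls <- calls
      results$percpg <- pc
    })
  } else note("methylation", "skipped: no beta-value input")

  # --- tissue atlas -------------------------------------------------------
  if (!is.null(dat$tissue)) {
    timed("tissue", {
      mu <- tissue_means(dat$tissue$expr, dat$tissue$tissue_labels)
      prof <- classify_liver_preferential(
        mu[top, , drop = FALSE], expr_floor = cfg$tissue$expr_floor,
        similarity_ratio = cfg$tissue$similarity_ratio, k = cfg$tissue$k)
      labs <- dat$tissue$tissue_labels
      fetal <- names(labs)[labs == "fetal_liver"]
      adult <- names(labs)[labs == "liver"]
      if (length(fetal) >= 2L) {
        fc <- fetal_adult_contrast(dat$tissue$expr, fetal, adult, genes = top)
        prof <- merge(prof, fc, by = "gene_id")
      }
      utils::write.table(prof, file.path(cfg$out_dir, "tissue_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$tissue_profile <- prof
    })
  } else note("tissue", "skipped: no tissue-panel input")

  # --- clinical outcomes --------------------------------------------------
  if (!is.null(dat$clinical)) {
    timed("clinical", {
      tumor <- names(dat$condition)[dat$condition == "tumor"]
      tumor <- intersect(tumor, dat$clinical$sample_id)
      score <- signature_score(lc[, tumor, drop = FALSE], top)
      sub <- stratify_extremes(score, k = cfg$clinical$k)
      cl <- dat$clinical[match(tumor, dat$clinical$sample_id), ]

      corr <- NULL
      if (!is.null(dat$truth$liver_sig_genes)) {
        sig_score <- signature_score(lc[, tumor, drop = FALSE],
                                     dat$truth$liver_sig_genes)
        corr <- spearman_corr(score, sig_score)
      }
      keep <- !is.na(sub)
      lr <- logrank_test(cl$os_time[keep], cl$os_event[keep], sub[keep])
      km <- lapply(split(seq_len(sum(keep)),
                         sub[keep]), function(i) {
        km_estimate(cl$os_time[keep][i], cl$os_event[keep][i])
      })
      grade_tab <- table(sub[keep], as.character(cl$grade[keep]))
      grade_enr <- categorical_enrichment(grade_tab)
      pgs <- per_gene_survival(lc[top, tumor, drop = FALSE], cl)

      utils::write.table(
        data.frame(sample_id = tumor, score = score, subgroup = sub),
        file.path(cfg$out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      km_tab <- do.call(rbind, lapply(names(km), function(g)
        cbind(group = g, km[[g]])))
      utils::write.table(km_tab, file.path(cfg$out_dir, "km_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pgs$table,
                         file.path(cfg$out_dir, "per_gene_survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$clinical <- list(score = score, subgroups = sub,
                                spearman = corr, logrank = lr, km = km,
                                grade_enrichment = grade_enr,
                                per_gene_survival = pgs)
    })
  } else note("clinical", "skipped: no clinical input")

  # --- guilt-by-association ----------------------------------------------
  gsets <- dat$gene_sets
  if (is.null(gsets) && !is.null(dat$truth$liver_sig_genes)) {
    # synthetic mode: the planted liver signature plus a random control set
    set.seed(child_seed(cfg$seed, "gba_sets"))
    coding <- dat$annot$gene_id[dat$annot$biotype == "coding"]
    gsets <- list(LIVER_SIGNATURE = dat$truth$liver_sig_genes,
                  RANDOM_CONTROL = sort(sample(coding, 50L)))
  }
  if (!is.null(gsets) && length(top) > 0L) {
    timed("gba", {
      coding <- dat$annot$gene_id[dat$annot$biotype == "coding"]
      targets <- utils::head(top, cfg$gba$n_targets)
      gba <- lapply(targets, function(tg)
        gba_analysis(lc[, names(dat$condition)[dat$condition == "tumor"],
                        drop = FALSE],
                     tg, coding, gsets, p_w = cfg$gba$p_w,
                     n_perm = cfg$gba$n_perm, seed = cfg$seed))
      names(gba) <- targets
      gba_tab <- do.call(rbind, lapply(targets, function(tg)
        cbind(target = tg, gba[[tg]]$gsea)))
      utils::write.table(gba_tab, file.path(cfg$out_dir, "gba.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$gba <- gba
    })
  } else note("gba", "skipped: no gene sets / no top genes")

  report$output_md5 <- as.list(tools::md5sum(
    list.files(cfg$out_dir, pattern = "\\.(tsv|txt)$", full.names = TRUE)))
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$results <- results
  invisible(report)
}
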
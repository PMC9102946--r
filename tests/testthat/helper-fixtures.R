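# Shared fixtures, built in code. The full-scale default cohort (the
# study conditions: 50 normals, 374 tumors, ~2000 genes, 35 planted
# lncRNAs) is expensive, so it is generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort for unit tests: quick but structurally complete
small_cohort <- function(seed = 1L) {
  memo(paste0("small_", seed), {
    aa <- generate_annotation(200, 60, seed = seed)
    cc <- generate_cohort_counts(aa$annot, n_normal = 12L, n_tumor = 40L,
                                 n_planted_down = 10L, n_liver_sig = 40L,
                                 seed = seed)
    c(aa, cc)
  })
}

# the full default study-condition cohort
default_cohort <- function(seed = 1L) {
  memo(paste0("default_", seed), {
    aa <- generate_annotation(1500, 500, seed = seed)
    cc <- generate_cohort_counts(aa$annot, seed = seed)
    c(aa, cc)
  })
}

# full default pipeline run (R = 200), reused by several acceptance checks
default_pipeline_run <- function(seed = 1L) {
  memo(paste0("pipeline_", seed), {
    out <- file.path(tempdir(), paste0("hepident_accept_", seed))
    rep <- run_pipeline(list(seed = seed, out_dir = out,
                             gba = list(n_perm = 500L)))
    rep$truth <- read_truth(file.path(out, "synthetic", "truth.json"))
    rep
  })
}

# brute-force signed-rank null tail: P(W >= w) for n signs, by the
# convolution polynomial over rank sums (independent of stats::psignrank)
signed_rank_tail <- function(w, n) {
  counts <- c(1, rep(0, n * (n + 1) / 2))  # counts[s+1] = #subsets with sum s
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  sum(counts[(w + 1):length(counts)]) / 2^n
}
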
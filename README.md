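# hepident

Consensus identification of liver-identity lncRNAs silenced in
hepatocellular carcinoma (HCC).

## The problem

A recurring observation in liver cancer genomics is that a set of long
non-coding RNAs highly expressed in healthy adult liver is strongly
downregulated in tumors, that their promoters become DNA-hypermethylated,
and that losing them tracks with loss of hepatocyte identity, higher
tumor grade and worse survival. Testing that chain of claims requires a
pipeline with several coupled stages — robust differential expression on
a very asymmetric cohort (tens of normals, hundreds of tumors), promoter
methylation calling from CpG beta-values, tissue-preference
classification, signature scoring, survival analysis and functional
enrichment. `hepident` implements that pipeline as tested, reusable R
functions, and ships a synthetic-cohort generator with planted ground
truth so the whole chain can be validated end to end without any
controlled-access download.

## The core method

The screen is a **subsampling consensus**: with all $n_N$ normal samples
fixed, draw 50 of the tumors at random, run
TMM → log2-CPM → moderated-t → Benjamini-Hochberg on the subsample, and
record which genes reach $q < 0.01$ with negative log fold change;
repeat $R = 200$ times and retain only genes significant in **every**
iteration. The top set is then the 35 retained genes with full-cohort
$\log_2\mathrm{FC} < -3.5$ and $q < 0.05$, ranked most-downregulated
first. The moderated t shrinks gene-wise variances
$s^2_g$ toward an empirical-Bayes prior $(d_0, s_0^2)$ estimated by
trigamma moment inversion:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \hat\beta_g \Big/ \sqrt{\tilde s_g^2\,(1/n_1+1/n_2)},$$

Downstream stages: strand-aware 5 kb upstream promoter windows with
exact (tie-robust) signed-rank hypermethylation calling; a
more-than-three-similar-tissues rule separating liver-preferential from
ubiquitous genes plus a fetal-vs-adult liver contrast; mean-expression
signature scores, Spearman correlation against a liver-identity gene
set, extreme-45 patient stratification with Kaplan-Meier/log-rank
survival and Fisher/chi-squared clinical enrichment; and preranked
guilt-by-association GSEA with a gene-label permutation null. Details
and design rationale are in `vignettes/hepident-methods.Rmd`.

## Worked example

```r
library(hepident)

rep <- run_pipeline(list(seed = 1, out_dir = "demo_run"))
r <- rep$results
truth <- read_truth("demo_run/synthetic/truth.json")

length(r$top_genes)                         # 35
setequal(r$top_genes, names(truth$de_genes))# TRUE — planted set recovered
table(r$promoter_calls$hypermethylated)     # FALSE 17, TRUE 18
r$clinical$spearman$rho                     # 0.9216 (top-set vs liver signature)
r$clinical$logrank$p                        # 6.01e-12 (subgroup #1 vs #2)
r$clinical$per_gene_survival$n_significant  # 32 of 35 genes
```

This synthesizes the default cohort (50 normals, 374 tumors, ~2,000
genes, 35 planted downregulated lncRNAs), runs all stages (about 40 s),
and writes TSV outputs plus a JSON run report under `demo_run/`. The
numbers above are what the default seed prints: the consensus recovers
exactly the 35 planted lncRNAs with zero null retention; 18 of them were
planted with promoter hypermethylation and exactly those 18 are called;
17 are classified liver-preferential (the planted split); the top-set
score correlates strongly with the liver-signature score across the 374
synthetic patients; and the low-expression patient subgroup has
significantly worse survival, in the direction planted through the
latent differentiation factor.

A thin command-line front end is included at `inst/cli/hepident`
(`hepident synth`, `hepident run`), forwarding to the same functions.

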
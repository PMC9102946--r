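# Signature scores, Spearman correlation with exact small-n p, extreme-k
# stratification, categorical enrichment, Kaplan-Meier and log-rank —
# each against a hand computation or an enumeration/permutation oracle.

test_that("signature score equals the brute-force mean over set rows", {
  set.seed(16)
  expr <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  set <- sample(rownames(expr), 20)
  sc <- signature_score(expr, set)
  brute <- apply(expr[set, ], 2, function(col) sum(col) / length(col))
  expect_equal(sc, brute)
  expect_equal(signature_score(expr, "g3"), expr["g3", ])
  expr["g1", ] <- 5
  expect_equal(unname(signature_score(expr, "g1")), rep(5, 10))
  expect_error(signature_score(expr, c("nope1", "nope2")), "no signature gene")
  expect_message(signature_score(expr, c("g1", "nope")), "absent")
})

test_that("Spearman rho matches the hand rank formula and its limits", {
  r <- spearman_corr(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$rho, -0.5)  # 1 - 6*6/(3*8)
  expect_equal(spearman_corr(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_corr(1:8, exp(-(1:8)))$rho, -1)
  expect_error(spearman_corr(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_corr(1:4, 1:5), "paired")
})

test_that("exact Spearman p agrees with full permutation enumeration", {
  set.seed(17)
  x <- rnorm(7); y <- rnorm(7)
  r <- spearman_corr(x, y)
  expect_equal(r$method, "exact")
  # enumerate all 7! rank permutations
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  null_rho <- vapply(perms(1:7), function(p) cor(p, ry), numeric(1))
  p_enum <- mean(abs(null_rho) >= abs(rho_obs) - 1e-12)
  expect_equal(r$p, p_enum, tolerance = 1e-10)
  # large-n path uses the t approximation
  set.seed(18)
  big <- spearman_corr(rnorm(50), rnorm(50))
  expect_equal(big$method, "t-approximation")
})

test_that("extreme-k stratification assigns top and bottom deterministically", {
  s <- setNames(c(5, 1, 3, 2, 4, 6), paste0("p", 1:6))
  sub <- stratify_extremes(s, k = 3)
  expect_equal(unname(sub[c("p1", "p5", "p6")]), rep("#1", 3))
  expect_equal(unname(sub[c("p2", "p3", "p4")]), rep("#2", 3))
  sub1 <- stratify_extremes(s, k = 1)
  expect_equal(names(which(sub1 == "#1")), "p6")
  expect_equal(names(which(sub1 == "#2")), "p2")
  expect_true(sum(is.na(sub1)) == 4)
  expect_error(stratify_extremes(s, k = 4), "exceeds")
  # tied boundary resolved by id, with a message
  st <- setNames(c(1, 1, 1, 2), paste0("q", 1:4))
  expect_message(subt <- stratify_extremes(st, k = 2), "ties")
  expect_equal(names(which(subt == "#2")), c("q1", "q2"))
})

test_that("categorical enrichment picks Fisher for sparse 2x2, chi-squared else", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- categorical_enrichment(flat)
  expect_equal(res$method, "chi-squared")
  expect_equal(res$p, 1)

  sparse <- matrix(c(8, 1, 2, 9), 2)  # [[8,2],[1,9]] has expected < 5
  res2 <- categorical_enrichment(sparse)
  expect_equal(res2$method, "fisher")
  # full hypergeometric enumeration: condition on margins (10, 10 | 9, 11)
  p_tab <- function(a) dhyper(a, 10, 10, 9)
  probs <- vapply(0:9, p_tab, numeric(1))
  p_enum <- sum(probs[probs <= p_tab(8) * (1 + 1e-7)])
  expect_equal(res2$p, p_enum, tolerance = 1e-10)
  expect_error(categorical_enrichment(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km4 <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km4$surv, c(0.75, 0.5, 0.25, 0))
  # events at 2 and 4, censored at 3: risk sets {3, 1}
  km <- km_estimate(c(2, 3, 4), c(1, 0, 1))
  expect_equal(km$surv[km$time == 2], 2 / 3)
  expect_equal(km$surv[km$time == 4], 0)
  allc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(allc$surv == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank reproduces the hand O/E/V accumulation", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(lr$chisq, (2 - 5 / 6)^2 / 0.472222, tolerance = 1e-3)
  expect_equal(lr$chisq, 2.882353, tolerance = 1e-6)
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                       rep(c("a", "b"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("log-rank p agrees with a permutation null on toy data", {
  set.seed(19)
  times <- c(rexp(12, 1), rexp(12, 2.2))
  events <- rep(1, 24)
  groups <- rep(c("a", "b"), each = 12)
  lr <- logrank_test(times, events, groups)
  nperm <- 2000
  perm_chisq <- replicate(nperm, {
    survival::survdiff(survival::Surv(times, events) ~ sample(groups))$chisq
  })
  p_perm <- mean(perm_chisq >= lr$chisq)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(lr$p - p_perm), 2 * se + 0.01)
})

test_that("per-gene survival skips constant genes and finds coupled ones", {
  set.seed(20)
  n <- 120
  ids <- sprintf("T%03d", 1:n)
  expr <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("flat", "coupled", "noise"), ids))
  expr["flat", ] <- 1
  scores <- expr["coupled", ]
  cl <- generate_clinical(setNames(scores, ids), gamma = -1.2,
                          censor_rate = 0.2, seed = 20)
  res <- NULL
  expect_warning(res <- per_gene_survival(expr, cl), "constant")
  expect_false("flat" %in% res$table$gene_id)
  expect_lt(res$table$p[res$table$gene_id == "coupled"], 0.05)
})
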
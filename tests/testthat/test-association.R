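test_that("gene-region methylation counts match a brute-force overlap oracle", {
  sim <- get_sim()
  genes <- sim$features[sim$features$kind == "gene", ][1:10, ]
  sites <- call_modified_sites(sim$report_A)
  long <- gene_region_methylation(sites, genes)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    pos0 <- sites$pos - 1L
    for (rg in c("upstream", "body", "downstream")) {
      iv <- switch(rg,
        body = c(g$start, g$end),
        upstream = if (g$strand == "+") c(g$start - 2000L, g$start) else c(g$end, g$end + 2000L),
        downstream = if (g$strand == "+") c(g$end, g$end + 2000L) else c(g$start - 2000L, g$start))
      sel <- sites$chrom == g$chrom & pos0 >= iv[1] & pos0 < iv[2] &
        sites$context == "CG"
      row <- long[long$gene == g$id & long$region == rg & long$context == "CG", ]
      expect_equal(row$mc_count, sum(sites$modified[sel]))
      if (any(sel)) expect_equal(row$mean_level, mean(sites$level[sel]))
      else expect_true(is.na(row$mean_level))
    }
  }
})

test_that("covariate matrix holds one mC count per gene region", {
  gene <- feature_table("g1", "chr1", 10000L, 12000L, "+", "gene")
  sites <- call_modified_sites(make_report(c(9001L, 10500L, 10600L, 12500L),
                                           meth = 5L, total = 10L))
  X <- methylation_covariates(sites, gene, context = "CG")
  expect_equal(unname(X["g1", ]), c(1, 2, 1))
  # no covering cytosines -> all-zero covariates, not an error
  empty <- methylation_covariates(sites[0, ], gene, context = "CG")
  expect_equal(unname(empty["g1", ]), c(0, 0, 0))
})

test_that("Spearman association reproduces rank arithmetic and labels", {
  res <- spearman_assoc(c(1, 2, 3), c(3, 2, 1))
  expect_equal(res$rho, -1)
  # tie-corrected rho equals an independent rank-and-correlate oracle
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  res <- spearman_assoc(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_assoc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_assoc(c(1, 2), c(1, 2)), "at least 3")
  # strength labels, including the [0.79, 0.8) gap mapping to strong
  expect_equal(spearman_strength(c(0.15, -0.25, 0.5, 0.65, 0.795, 0.85, 1)),
               c("very weak", "weak", "moderate", "strong", "strong",
                 "very strong", "very strong"))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- rnorm(50); y <- x + rnorm(50)
  r0 <- spearman_assoc(x, y)
  r1 <- spearman_assoc(exp(x), y)
  r2 <- spearman_assoc(x, y^3 + 5 * y)
  expect_equal(r0$rho, r1$rho, tolerance = 1e-12)
  expect_equal(r0$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r0$p, r1$p, tolerance = 1e-12)
})

test_that("hurdle fit recovers generative parameters on direct draws", {
  set.seed(31)
  n <- 2000L
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  b_zero <- c(0.3, 0.5, 0)     # intercept, x1, x2
  b_count <- c(1.2, -0.3, 0)
  theta <- 2
  p_pos <- plogis(b_zero[1] + X %*% b_zero[-1])
  mu <- exp(b_count[1] + X %*% b_count[-1])
  pos <- rbinom(n, 1, p_pos) == 1
  y <- integer(n)
  p0 <- dnbinom(0, size = theta, mu = mu[pos])
  y[pos] <- pmax(1L, qnbinom(runif(sum(pos), p0, 1), size = theta, mu = mu[pos]))
  fit <- fit_hurdle(y, X)
  expect_true(fit$converged)
  expect_true(all(abs(fit$zero$estimate - b_zero) / fit$zero$se < 3))
  expect_true(all(abs(fit$count$estimate - b_count) / fit$count$se < 3))
  # a zero-truth slope is not called significant at any drastic level
  expect_gt(fit$count$p[3], 0.001)
  # MLE dominance: fitted likelihood beats the truth parameters
  ll_truth <- sum(dbinom(as.integer(y > 0), 1, p_pos, log = TRUE)) +
    sum(dnbinom(y[pos], size = theta, mu = mu[pos], log = TRUE) -
          log(1 - dnbinom(0, size = theta, mu = mu[pos])))
  expect_gte(fit$logLik, ll_truth)
})

test_that("tiny-instance hurdle likelihood matches a grid-search MLE", {
  set.seed(8)
  n <- 30L
  x <- rnorm(n)
  mu <- exp(1 + 0.5 * x)
  y <- rnbinom(n, size = 1.5, mu = mu)
  fit <- fit_hurdle(y, cbind(x = x))
  # zero part has a closed-form MLE via glm; grid-search the truncated NB part
  pos <- y > 0
  grid_best <- -Inf
  centre <- c(1, 0.5, log(1.5))
  for (round in 1:3) {
    b0s <- centre[1] + seq(-1, 1, length.out = 13) / round^2
    b1s <- centre[2] + seq(-1, 1, length.out = 13) / round^2
    lts <- centre[3] + seq(-1.5, 1.5, length.out = 13) / round^2
    for (b0 in b0s) for (b1 in b1s) for (lt in lts) {
      ll <- ztnb_loglik(b0, b1, exp(lt), y[pos], x[pos])
      if (ll > grid_best) {
        grid_best <- ll
        centre <- c(b0, b1, lt)
      }
    }
  }
  ll_zero <- as.numeric(logLik(glm((y > 0) ~ x, family = binomial())))
  expect_gte(fit$logLik, ll_zero + grid_best - 1e-3)
  expect_lte(fit$logLik, ll_zero + grid_best + 0.05)  # grid is only near-exact
  expect_error(fit_hurdle(rep(0L, 10), cbind(x = rnorm(10))), "both zero and positive")
  expect_error(fit_hurdle(rep(2L, 10), cbind(x = rnorm(10))), "both zero and positive")
})

test_that("negative-binomial fit recovers slopes and degenerates sensibly", {
  set.seed(41)
  n <- 2000L
  x <- rnorm(n)
  y <- rnbinom(n, size = 2, mu = exp(1 + 0.4 * x))
  fit <- fit_negbin(y, cbind(x = x))
  expect_true(abs(fit$count$estimate[2] - 0.4) / fit$count$se[2] < 3)
  # Poisson-like data: the overdispersion 1/theta shrinks toward zero
  yp <- rpois(n, exp(1 + 0.4 * x))
  fitp <- suppressWarnings(fit_negbin(yp, cbind(x = x)))
  expect_lt(1 / fitp$dispersion, 0.05)
  # intercept-only on constant counts: fitted mean equals the constant
  fc <- suppressWarnings(fit_negbin(rep(7L, 40), matrix(0, 40, 1)))
  expect_equal(unname(predict(fc, matrix(0, 1, 1))), 7, tolerance = 1e-6)
})

test_that("Q2 identity and bounds hold", {
  set.seed(51)
  n <- 200L
  X <- cbind(x = rnorm(n))
  y <- rnbinom(n, size = 2, mu = exp(1 + 0.8 * X[, 1]))
  y[sample(n, 60)] <- 0L
  # oracle predictor: the response itself is smuggled in as a covariate
  oracle <- list(fit = function(y, X) NULL,
                 predict = function(f, X) X[, "y_copy"])
  cv <- q2_cross_validate(y, cbind(X, y_copy = y), model = oracle, seed = 3)
  expect_equal(cv$Q2, 1)
  expect_equal(cv$PRESS, 0)
  # global-mean predictor can never beat the in-sample mean
  mean_pred <- list(fit = function(y, X) mean(y),
                    predict = function(f, X) rep(f, nrow(X)))
  cv0 <- q2_cross_validate(y, X, model = mean_pred, seed = 3)
  expect_lte(cv0$Q2, 0)
  # identity Q2 = 1 - PRESS/TSS holds exactly for a real model
  cvh <- q2_cross_validate(y, X, model = "hurdle", k = 10, seed = 11)
  expect_identical(cvh$Q2, 1 - cvh$PRESS / cvh$TSS)
  expect_lte(cvh$Q2, 1)
  expect_error(q2_cross_validate(y[1:5], X[1:5, , drop = FALSE], k = 10),
               "at least k")
})

test_that("Fisher comparisons match hypergeometric enumeration", {
  # balanced table: p = 1
  expect_equal(fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  # extreme 2x2: only the two extreme tables are as unlikely
  expect_equal(fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               2 / choose(20, 10), tolerance = 1e-12)
  # implementation vs full enumeration over all tables with the same margins
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    probs <- dhyper(max(0, k - n):min(k, m), m, n, k)
    obs <- dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  for (seed in 1:20) {
    set.seed(seed)
    t <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher.test(t)$p.value,
                 enum_fisher(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 tolerance = 1e-7, info = paste("seed", seed))
  }
})

test_that("siRNA-covered cytosines are more methylated in the simulation", {
  sim <- get_sim()
  res <- sirna_overlap_compare(sim$report_A, sim$sirna)
  chh <- res[res$context == "CHH", ]
  expect_gt(chh$level_covered, chh$level_uncovered)
  expect_lt(chh$p, 0.01)
  # sites unit variant runs and agrees on direction
  res_sites <- sirna_overlap_compare(sim$report_A, sim$sirna, unit = "sites")
  expect_gt(res_sites$level_covered[3], res_sites$level_uncovered[3])
  expect_error(sirna_overlap_compare(sim$report_A, sim$sirna[0, ]), "empty partition")
})

test_that("siRNA density in TEs decays with distance to the nearest gene", {
  sim <- get_sim()
  tes <- sim$features[sim$features$kind == "TE", ]
  genes <- sim$features[sim$features$kind == "gene", ]
  prof <- sirna_gene_distance_profile(sim$sirna, tes, genes,
                                      breaks = c(0, 2000, Inf))
  near <- prof$mean_sirna_per_bp[1]
  far <- prof$mean_sirna_per_bp[nrow(prof)]
  expect_gt(near, far)
  # a TE overlapping a gene is at distance 0
  expect_equal(nearest_gene_distance(
    feature_table("t", "chr1", 100L, 200L, "+", "TE", te_family = "hAT"),
    feature_table("g", "chr1", 150L, 400L, "+", "gene")), 0)
  # no siRNA at all -> all-zero densities
  prof0 <- sirna_gene_distance_profile(sim$sirna[0, ], tes, genes)
  expect_true(all(prof0$mean_sirna_per_bp == 0 | is.na(prof0$mean_sirna_per_bp)))
})
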
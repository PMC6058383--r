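test_that("gap chaining produces the documented maximal runs", {
  # usable sites at 1-based positions 100, 250, 600: the 150 bp gap chains,
  # the 350 bp gap splits
  a <- make_report(c(100L, 250L, 600L), meth = 10L, total = 12L)
  b <- make_report(c(100L, 250L, 600L), meth = 1L, total = 12L)
  cand <- candidate_regions(a, b, "CG")
  expect_equal(cand$start, c(99L, 599L))
  expect_equal(cand$end, c(250L, 600L))
  expect_equal(cand$n_sites, c(2L, 1L))
  # a gap of exactly max_gap splits (the rule is strictly less-than)
  a2 <- make_report(c(100L, 300L), meth = 10L, total = 12L)
  b2 <- make_report(c(100L, 300L), meth = 1L, total = 12L)
  expect_equal(nrow(candidate_regions(a2, b2, "CG")), 2L)
  # no usable sites -> empty
  expect_equal(nrow(candidate_regions(a[0, ], b[0, ], "CG")), 0L)
  # low coverage in one tissue makes a site unusable
  b3 <- make_report(c(100L, 250L, 600L), meth = 1L, total = c(12L, 5L, 12L))
  expect_equal(candidate_regions(a, b3, "CG")$n_sites, c(1L, 1L))
})

test_that("region evaluation applies the six criteria in order", {
  params <- dmr_params()
  # identical counts: fold change 1, rejected
  pos <- seq(1000L, 1400L, by = 50L)
  a <- make_report(pos, meth = 8L, total = 16L)
  ev <- evaluate_region(data.frame(chrom = "chr1", start = 999L, end = 1400L),
                        a, a, "CG", params)
  expect_false(ev$pass)
  expect_equal(ev$reason, "fold_change")
  # 30 bp candidate: length rejection
  short_a <- make_report(c(1000L, 1010L, 1020L), meth = 10L, total = 12L)
  short_b <- make_report(c(1000L, 1010L, 1020L), meth = 1L, total = 12L)
  ev <- evaluate_region(data.frame(chrom = "chr1", start = 999L, end = 1020L),
                        short_a, short_b, "CG", params)
  expect_equal(ev$reason, "length")
  # fewer than 5 methylated cytosines in both tissues
  few_a <- make_report(c(1000L, 1100L, 1200L), meth = 10L, total = 12L)
  few_b <- make_report(c(1000L, 1100L, 1200L), meth = 1L, total = 12L)
  ev <- evaluate_region(data.frame(chrom = "chr1", start = 999L, end = 1200L),
                        few_a, few_b, "CG", params)
  expect_equal(ev$reason, "methylated_sites")
  # degenerate pooled table: all reads methylated in both tissues
  deg_a <- make_report(pos, meth = 16L, total = 16L)
  deg_b <- make_report(pos, meth = c(rep(16L, 8L), 1L), total = 16L)
  ev <- evaluate_region(data.frame(chrom = "chr1", start = 999L, end = 1400L),
                        deg_a, deg_a, "CG",
                        dmr_params(fold_min = 0.5))
  expect_equal(ev$reason, "degenerate_table")
})

test_that("pooled chi-square matches the closed form", {
  # pooled table meth/unmeth = (40,10) vs (10,40):
  # chi2 = n(ad-bc)^2 / (r1 r2 c1 c2) = 36
  pos <- seq(1000L, 1240L, by = 60L)
  a <- make_report(pos, meth = 8L, total = 10L)
  b <- make_report(pos, meth = 2L, total = 10L)
  ev <- evaluate_region(data.frame(chrom = "chr1", start = 999L, end = 1240L),
                        a, b, "CG")
  expect_true(ev$pass)
  expect_equal(ev$chi2, 36)
  expect_equal(ev$p, pchisq(36, 1, lower.tail = FALSE))
  expect_equal(ev$p, 1.97e-9, tolerance = 1e-3)
  expect_equal(ev$direction, "hyper")
  expect_equal(ev$fold_change, (0.8 + 0.001) / (0.2 + 0.001))
})

test_that("maximal-run calling equals the brute-force enumerator on random instances", {
  for (seed in 1:200) {
    inst <- random_dmr_instance(seed)
    got <- call_dmrs(inst$A, inst$B, contexts = "CG", segment = FALSE)
    want <- brute_force_dmrs(inst$A, inst$B, "CG")
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want) > 0L) {
      expect_equal(got$start, want$start, info = paste("seed", seed))
      expect_equal(got$end, want$end, info = paste("seed", seed))
      expect_equal(got$level_A, want$level_A, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-9)
      expect_equal(got$direction, want$direction)
    }
  }
})

test_that("segmentation is a no-op on candidates that already pass", {
  for (seed in 1:50) {
    inst <- random_dmr_instance(seed)
    plain <- call_dmrs(inst$A, inst$B, contexts = "CG", segment = FALSE)
    seg <- call_dmrs(inst$A, inst$B, contexts = "CG", segment = TRUE)
    # every maximal run that passes outright must be reported identically
    if (nrow(plain) > 0L) {
      key_plain <- paste(plain$chrom, plain$start, plain$end)
      key_seg <- paste(seg$chrom, seg$start, seg$end)
      expect_true(all(key_plain %in% key_seg), info = paste("seed", seed))
    }
  }
})

test_that("segmentation recovers a differential interval inside a uniform run", {
  # 2 kb of uniform background with a 400 bp contrasted interval in the middle
  pos <- seq(1001L, 3000L, by = 20L)
  inside <- pos >= 1801L & pos <= 2200L
  set.seed(5)
  tot_a <- rpois(length(pos), 25) + 1L
  tot_b <- rpois(length(pos), 25) + 1L
  a <- make_report(pos, rbinom(length(pos), tot_a, ifelse(inside, 0.85, 0.5)), tot_a)
  b <- make_report(pos, rbinom(length(pos), tot_b, ifelse(inside, 0.15, 0.5)), tot_b)
  plain <- call_dmrs(a, b, contexts = "CG", segment = FALSE)
  seg <- call_dmrs(a, b, contexts = "CG", segment = TRUE)
  expect_equal(nrow(plain), 0L)  # the maximal run is diluted below the fold bound
  expect_gt(nrow(seg), 0L)
  cov <- sum(pmin(seg$end, 2200L) - pmax(seg$start, 1800L))
  expect_gt(cov / 400, 0.5)
})

test_that("tissue swap preserves intervals and p-values and flips direction", {
  sim <- get_sim()
  ab <- call_dmrs(sim$report_A, sim$report_B, contexts = "CG")
  ba <- call_dmrs(sim$report_B, sim$report_A, contexts = "CG")
  expect_equal(ab[c("chrom", "start", "end", "n_sites")],
               ba[c("chrom", "start", "end", "n_sites")])
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$level_A, ba$level_B, tolerance = 1e-12)
  expect_equal(ifelse(ab$direction == "hyper", "hypo", "hyper"), ba$direction)
})

test_that("tightening any threshold never adds a DMR", {
  sim <- get_sim()
  base <- call_dmrs(sim$report_A, sim$report_B, contexts = "CG")
  key <- function(d) paste(d$chrom, d$start, d$end)
  stricter <- list(
    dmr_params(alpha = 0.001),
    dmr_params(fold_min = 3),
    dmr_params(min_cov = 15),
    dmr_params(min_mc = 10)
  )
  for (p in stricter) {
    d <- call_dmrs(sim$report_A, sim$report_B, contexts = "CG", params = p)
    expect_lte(nrow(d), nrow(base))
  }
  # relaxing the chi-square criterion (alpha = 1) can only add calls
  relaxed <- call_dmrs(sim$report_A, sim$report_B, contexts = "CG",
                       params = dmr_params(alpha = 1))
  expect_gte(nrow(relaxed), nrow(base))
})

test_that("planted DMRs are recovered and identical tissues yield none", {
  sim <- get_sim()
  dmrs <- call_dmrs(sim$report_A, sim$report_B, contexts = "CG")
  truth <- sim$truth$dmrs
  expect_gte(dmr_recall(dmrs, truth), 0.9)
  # every called CG DMR overlaps a planted interval (background CG is null)
  fp <- vapply(seq_len(nrow(dmrs)), function(i) {
    !any(truth$chrom == dmrs$chrom[i] & truth$end > dmrs$start[i] &
           truth$start < dmrs$end[i])
  }, TRUE)
  expect_equal(sum(fp), 0L)
  expect_true(all(dmrs$direction == "hyper"))  # planted 0.8 vs 0.2
  # identical input twice: no DMRs at all
  null <- call_dmrs(sim$report_A, sim$report_A, contexts = "CG")
  expect_equal(nrow(null), 0L)
})

test_that("chi-square criterion alone is calibrated on null candidates", {
  # many sparse null candidates drawn at the same level in both tissues;
  # only the chi-square criterion active
  params <- dmr_params(min_mc = 0L, fold_min = 0, alpha = 0.05)
  set.seed(99)
  n_rep <- 400L
  pass <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    pos <- sort(sample(1000:1900, 10L))
    ta <- rpois(10L, 25) + 1L
    tb <- rpois(10L, 25) + 1L
    a <- make_report(pos, rbinom(10L, ta, 0.5), ta)
    b <- make_report(pos, rbinom(10L, tb, 0.5), tb)
    ev <- evaluate_region(data.frame(chrom = "chr1", start = min(pos) - 1L,
                                     end = max(pos)), a, b, "CG", params)
    pass[i] <- ev$pass
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(pass) - 0.05), 3 * se)
})

test_that("DMR summaries count directions per context", {
  dmrs <- data.frame(
    chrom = "chr1", start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    context = "CG", n_sites = 5L, level_A = c(0.8, 0.8, 0.8, 0.2),
    level_B = c(0.2, 0.2, 0.2, 0.8), fold_change = 4, chi2 = 36, p = 1e-9,
    direction = c("hyper", "hyper", "hyper", "hypo"), stringsAsFactors = FALSE)
  s <- summarize_dmrs(dmrs)
  expect_equal(s$pct_hyper[s$context == "CG"], 75)
  expect_true(is.na(s$pct_hyper[s$context == "CHH"]))
  empty <- summarize_dmrs(dmrs[0, ])
  expect_equal(empty$n, c(0L, 0L, 0L))
  # planted truth directions are reproduced
  sim <- get_sim()
  called <- call_dmrs(sim$report_A, sim$report_B, contexts = "CG")
  s2 <- summarize_dmrs(called)
  expect_equal(s2$pct_hyper[s2$context == "CG"], 100)
})

test_that("DMRs map to gene regions with strand-aware flanks", {
  genes <- feature_table(id = c("gp", "gm"), chrom = "chr1",
                         start = c(10000L, 30000L), end = c(12000L, 32000L),
                         strand = c("+", "-"), kind = "gene")
  dmr <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                   context = "CG", n_sites = 6L, level_A = 0.8,
                                   level_B = 0.2, fold_change = 4, chi2 = 36,
                                   p = 1e-9, direction = "hyper",
                                   stringsAsFactors = FALSE)
  # wholly 500 bp 5' of the plus-strand TSS
  hit <- assign_dmr_to_genes(dmr(9400L, 9500L), genes)
  expect_equal(hit[, c("gene", "region")],
               data.frame(gene = "gp", region = "upstream"))
  # the same offset left of a minus-strand gene is its 3' side
  hit <- assign_dmr_to_genes(dmr(29400L, 29500L), genes)
  expect_equal(hit[, c("gene", "region")],
               data.frame(gene = "gm", region = "downstream"))
  # spanning the TSS yields both the upstream and the body triple
  hit <- assign_dmr_to_genes(dmr(9900L, 10100L), genes)
  expect_setequal(hit$region, c("upstream", "body"))
  expect_equal(nrow(assign_dmr_to_genes(dmr(50000L, 50100L), genes)), 0L)
})

test_that("term enrichment matches hypergeometric enumeration and BH", {
  universe <- sprintf("g%03d", 1:100)
  term_map <- list(T1 = universe[1:10], T2 = universe)
  hits <- universe[c(1:5, 11:15)]
  res <- term_enrichment(hits, universe, term_map)
  # direct enumeration: P(overlap >= 5) for K = 10, n = 10, N = 100
  p_oracle <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(res$p[res$term == "T1"], p_oracle, tolerance = 1e-12)
  # a term equal to the universe is never enriched
  expect_equal(res$p[res$term == "T2"], 1)
  # BH arithmetic on two raw p-values
  expect_equal(p.adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
  expect_error(term_enrichment("zzz", universe, term_map), "outside")
  expect_error(term_enrichment("g001", character(), term_map), "empty")
})
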
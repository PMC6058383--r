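# shared fixtures and independent oracles for the test suite

# memoized default simulation so several files can share one run
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function(seed = 11L, ...) {
  key <- paste0("seed", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_study(sim_config(seed = seed, ...))
  }
  .sim_cache[[key]]
}

# quick single-strand cytosine report builder
make_report <- function(pos, meth, total, context = "CG", chrom = "chr1",
                        strand = "+") {
  tri <- c(CG = "CGA", CHG = "CAG", CHH = "CAA")[context]
  cytosine_report(chrom = rep_len(chrom, length(pos)), pos = pos,
                  strand = rep_len(strand, length(pos)),
                  context = rep_len(context, length(pos)),
                  meth = meth, total = total, tri = rep_len(tri, length(pos)))
}

# random valid report rows for round-trip property tests
random_report <- function(n, seed) {
  set.seed(seed)
  ctx <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE)
  b2 <- ifelse(ctx == "CG", "G", sample(c("A", "T", "C"), n, replace = TRUE))
  b3 <- ifelse(ctx == "CHG", "G",
               sample(c("A", "T", "C"), n, replace = TRUE))
  b3[ctx == "CG"] <- sample(c("A", "C", "G", "T"), sum(ctx == "CG"), replace = TRUE)
  total <- sample(1:50, n, replace = TRUE)
  cytosine_report(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample(1:100000, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = ctx,
    meth = vapply(total, function(t) sample(0:t, 1L), 0L),
    total = total,
    tri = paste0("C", b2, b3)
  )
}

# --- independent brute-force DMR enumerator ----------------------------------
# Re-derives the maximal gap-run + six-criteria algorithm from first
# principles: merge() for the tissue join, explicit run scanning, plain sums
# for the region statistics and stats::chisq.test for the chi-square.
brute_force_dmrs <- function(sites_A, sites_B, context, params = dmr_params()) {
  a <- sites_A[sites_A$context == context, ]
  b <- sites_B[sites_B$context == context, ]
  j <- merge(a, b, by = c("chrom", "pos", "strand"), suffixes = c("_A", "_B"))
  mod_A <- j$total_A >= params$call_min_cov & j$meth_A >= params$call_min_meth
  mod_B <- j$total_B >= params$call_min_cov & j$meth_B >= params$call_min_meth
  j <- j[j$total_A >= params$min_cov & j$total_B >= params$min_cov &
           (mod_A | mod_B), ]
  out <- list()
  for (cn in unique(j$chrom)) {
    jc <- j[j$chrom == cn, ]
    jc <- jc[order(jc$pos), ]
    # maximal runs: walk sites, break where the gap to the previous position
    # is >= max_gap
    run_id <- 1L
    runs <- integer(nrow(jc))
    runs[1L] <- run_id
    for (i in seq_len(nrow(jc))[-1L]) {
      if (jc$pos[i] - jc$pos[i - 1L] >= params$max_gap) run_id <- run_id + 1L
      runs[i] <- run_id
    }
    for (r in unique(runs)) {
      m <- jc[runs == r, ]
      start <- min(m$pos) - 1L
      end <- max(m$pos)
      len <- end - start
      if (len < params$min_len || len > params$max_len) next
      mc_A <- sum(m$total_A >= params$call_min_cov & m$meth_A >= params$call_min_meth)
      mc_B <- sum(m$total_B >= params$call_min_cov & m$meth_B >= params$call_min_meth)
      if (mc_A < params$min_mc && mc_B < params$min_mc) next
      lev_A <- mean(m$meth_A / m$total_A)
      lev_B <- mean(m$meth_B / m$total_B)
      fold <- (max(lev_A, lev_B) + params$eps) / (min(lev_A, lev_B) + params$eps)
      if (fold <= params$fold_min) next
      tab <- matrix(c(sum(m$meth_A), sum(m$total_A) - sum(m$meth_A),
                      sum(m$meth_B), sum(m$total_B) - sum(m$meth_B)),
                    nrow = 2L, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      if (p > params$alpha) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = start, end = end, n_sites = nrow(m),
        level_A = lev_A, level_B = lev_B, p = p,
        direction = if (lev_A > lev_B) "hyper" else "hypo",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), level_A = numeric(),
                      level_B = numeric(), p = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

# random small two-tissue instance for the oracle-equivalence tests
random_dmr_instance <- function(seed, n_max = 50L, span = 3000L) {
  set.seed(seed)
  n <- sample(5:n_max, 1L)
  pos <- sort(sample(seq_len(span), n))
  lev_A <- runif(1L, 0, 1)
  lev_B <- runif(1L, 0, 1)
  tot_A <- sample(5:40, n, replace = TRUE)
  tot_B <- sample(5:40, n, replace = TRUE)
  list(
    A = make_report(pos, rbinom(n, tot_A, lev_A), tot_A),
    B = make_report(pos, rbinom(n, tot_B, lev_B), tot_B)
  )
}

# planted-DMR recall: fraction of truth intervals covered >= `frac` of their
# length by called DMRs
dmr_recall <- function(dmrs, truth, frac = 0.5) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    d <- dmrs[dmrs$chrom == truth$chrom[i] & dmrs$end > truth$start[i] &
                dmrs$start < truth$end[i], , drop = FALSE]
    if (nrow(d) == 0L) return(0)
    sum(pmin(d$end, truth$end[i]) - pmax(d$start, truth$start[i])) /
      (truth$end[i] - truth$start[i])
  }, 0)
  mean(hit >= frac)
}

# mirror a report and features to the reverse-complement genome coordinates
mirror_report <- function(report, chrom_len) {
  out <- report
  out$pos <- chrom_len + 1L - report$pos
  out$strand <- ifelse(report$strand == "+", "-", "+")
  out[order(out$chrom, out$pos), ]
}
mirror_features <- function(features, chrom_len) {
  out <- features
  out$start <- chrom_len - features$end
  out$end <- chrom_len - features$start
  out$strand <- ifelse(features$strand == "+", "-", "+")
  out$exons <- lapply(features$exons, function(ex) {
    if (is.null(ex)) return(NULL)
    m <- cbind(start = chrom_len - ex[, 2L], end = chrom_len - ex[, 1L])
    m[order(m[, 1L]), , drop = FALSE]
  })
  out[order(out$chrom, out$start), ]
}

# independent zero-truncated NB log-likelihood for grid-search oracles
ztnb_loglik <- function(b0, b1, theta, y, x) {
  mu <- exp(b0 + b1 * x)
  p0 <- (theta / (theta + mu))^theta
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE) - log(1 - p0))
}
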
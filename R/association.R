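#' Gene-region methylation summary
#'
#' For each gene and each gene-oriented region (2-kb upstream flank, body,
#' 2-kb downstream flank) and context: the unweighted mean site level and
#' the count of called methylated cytosines. Regions with no covered site
#' get `NA` level and count 0.
#'
#' @param sites a cytosine report (run through [call_modified_sites()] if it
#'   lacks the `modified` flag).
#' @param genes gene features.
#' @param flank_bp flank width (default 2000).
#' @param contexts contexts to summarize (default all three).
#' @return a long `data.frame`: `gene, region, context, mean_level,
#'   mc_count`.
#' @export
gene_region_methylation <- function(sites, genes, flank_bp = 2000L,
                                    contexts = c("CG", "CHG", "CHH")) {
  if (is.null(sites$modified)) sites <- call_modified_sites(sites)
  by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  rows <- vector("list", nrow(genes) * 3L * length(contexts))
  ri <- 0L
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    idx <- by_chrom[[g$chrom]]
    pos0 <- if (is.null(idx)) integer() else sites$pos[idx] - 1L
    sel <- idx[pos0 >= g$start - flank_bp & pos0 < g$end + flank_bp]
    p0 <- sites$pos[sel] - 1L
    reg <- character(length(sel))
    body <- p0 >= g$start & p0 < g$end
    left <- p0 < g$start
    reg[body] <- "body"
    if (g$strand == "+") {
      reg[left] <- "upstream"; reg[!body & !left] <- "downstream"
    } else {
      reg[left] <- "downstream"; reg[!body & !left] <- "upstream"
    }
    for (rg in c("upstream", "body", "downstream")) {
      for (cx in contexts) {
        s <- sel[reg == rg & sites$context[sel] == cx]
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          gene = g$id, region = rg, context = cx,
          mean_level = if (length(s)) mean(sites$level[s]) else NA_real_,
          mc_count = sum(sites$modified[s]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Methylated-cytosine count covariates for regression
#'
#' The covariate matrix of the expression models: per gene, counts of called
#' methylated cytosines of one context in the upstream flank, body and
#' downstream flank (gene-oriented).
#'
#' @inheritParams gene_region_methylation
#' @param context single context.
#' @return numeric matrix (genes x 3), columns `upstream, body, downstream`,
#'   rownames the gene ids.
#' @export
methylation_covariates <- function(sites, genes, context = "CG",
                                   flank_bp = 2000L) {
  long <- gene_region_methylation(sites, genes, flank_bp, contexts = context)
  m <- matrix(0, nrow(genes), 3L,
              dimnames = list(genes$id, c("upstream", "body", "downstream")))
  m[cbind(match(long$gene, genes$id), match(long$region, colnames(m)))] <- long$mc_count
  m
}

#' Spearman correlation with strength labels
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t approximation (`exact = TRUE` switches to the exact null
#' distribution for small untied samples). The absolute rho is labelled with
#' the conventional strength scale: `< 0.2` very weak, `[0.2, 0.4)` weak,
#' `[0.4, 0.6)` moderate, `[0.6, 0.8)` strong, `[0.8, 1]` very strong (the
#' scale as usually quoted leaves `[0.79, 0.8)` unassigned; it maps to
#' "strong" here).
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite.
#' @param exact use the exact p-value for small tie-free samples.
#' @return a list: `rho, p, n, strength`.
#' @export
spearman_assoc <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  if (length(x) < 3L) .stopf("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) .stopf("constant vector: rho undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  rho <- unname(ct$estimate)
  list(rho = rho, p = ct$p.value, n = length(x), strength = spearman_strength(rho))
}

#' @rdname spearman_assoc
#' @param rho correlation value(s) in `[-1, 1]`.
#' @export
spearman_strength <- function(rho) {
  a <- abs(rho)
  ifelse(a < 0.2, "very weak",
         ifelse(a < 0.4, "weak",
                ifelse(a < 0.6, "moderate",
                       ifelse(a < 0.8, "strong", "very strong"))))
}

#' Tenfold cross-validated Q2
#'
#' Seeded random partition into `k` near-equal folds; for each fold the
#' model is fitted on the remainder and the held-out mean response
#' predicted. `Q2 = 1 - PRESS / TSS` with PRESS the held-out squared
#' prediction error and TSS the total sum of squares around the global
#' mean.
#'
#' @param y non-negative integer response counts.
#' @param X covariate matrix.
#' @param model `"hurdle"`, `"negbin"`, or a list with elements `fit(y, X)`
#'   and `predict(fit, X)` for a custom predictor.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return a list of class `cv_result`: `Q2, PRESS, TSS, k, seed,
#'   predictions`.
#' @export
q2_cross_validate <- function(y, X, model = "hurdle", k = 10L, seed = 1L) {
  n <- length(y)
  if (n < k) .stopf("need at least k observations")
  funs <- if (is.list(model)) {
    model
  } else if (model == "hurdle") {
    list(fit = function(y, X) fit_hurdle(y, X),
         predict = function(f, X) predict(f, X))
  } else if (model == "negbin") {
    list(fit = function(y, X) fit_negbin(y, X),
         predict = function(f, X) predict(f, X))
  } else .stopf("unknown model kind: %s", model)
  make_folds <- function(s) {
    set.seed(s)
    sample(rep_len(seq_len(k), n))
  }
  folds <- make_folds(seed)
  pred <- rep(NA_real_, n)
  for (attempt in 1:2) {
    ok <- TRUE
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- tryCatch(funs$fit(y[!test], X[!test, , drop = FALSE]),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        ok <- FALSE
        break
      }
      pred[test] <- funs$predict(fit, X[test, , drop = FALSE])
    }
    if (ok) break
    if (attempt == 2L) .stopf("degenerate fold even after reshuffling")
    folds <- make_folds(seed + 1L)  # one reshuffle, then give up
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) .stopf("constant response: TSS is zero")
  out <- list(Q2 = 1 - press / tss, PRESS = press, TSS = tss, k = k,
              seed = seed, predictions = pred)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: Q2 = %.4f (PRESS = %.2f, TSS = %.2f)\n",
              x$k, x$Q2, x$PRESS, x$TSS))
  invisible(x)
}

#' Compare methylation inside and outside siRNA-covered regions
#'
#' Cytosines are partitioned genome-wide into those covered by a 24-nt siRNA
#' locus and the rest; per context the unweighted mean site levels of the
#' two partitions are compared with a two-sided Fisher's exact test on the
#' pooled (methylated, unmethylated) read counts (or on modified-site
#' counts with `unit = "sites"`).
#'
#' @param sites a cytosine report.
#' @param loci siRNA loci (`chrom, start, end`, 0-based half-open).
#' @param unit pool `"reads"` (default) or count `"sites"`.
#' @return a `data.frame` per context: `context, level_covered,
#'   level_uncovered, n_covered, n_uncovered, p`.
#' @export
sirna_overlap_compare <- function(sites, loci, unit = c("reads", "sites")) {
  unit <- match.arg(unit)
  if (is.null(sites$modified)) sites <- call_modified_sites(sites)
  gr_s <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  gr_l <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end))
  covered <- GenomicRanges::countOverlaps(gr_s, gr_l) > 0L
  res <- lapply(.contexts, function(cx) {
    inc <- sites$context == cx
    cov_in <- covered & inc
    cov_out <- !covered & inc
    if (!any(cov_in) || !any(cov_out)) .stopf("empty partition for context %s", cx)
    tab <- if (unit == "reads") {
      matrix(c(sum(sites$meth[cov_in]), sum(sites$total[cov_in]) - sum(sites$meth[cov_in]),
               sum(sites$meth[cov_out]), sum(sites$total[cov_out]) - sum(sites$meth[cov_out])),
             nrow = 2L, byrow = TRUE)
    } else {
      matrix(c(sum(sites$modified[cov_in]), sum(cov_in) - sum(sites$modified[cov_in]),
               sum(sites$modified[cov_out]), sum(cov_out) - sum(sites$modified[cov_out])),
             nrow = 2L, byrow = TRUE)
    }
    p <- fisher.test(tab)$p.value
    data.frame(context = cx,
               level_covered = mean(sites$level[cov_in]),
               level_uncovered = mean(sites$level[cov_out]),
               n_covered = sum(cov_in), n_uncovered = sum(cov_out),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' siRNA density in TEs by distance to the nearest gene
#'
#' Each TE is assigned its distance to the nearest gene (0 when
#' overlapping); per distance bin the mean number of siRNA loci per TE per
#' bp is reported.
#'
#' @param loci siRNA loci (`chrom, start, end`).
#' @param tes TE features.
#' @param genes gene features.
#' @param breaks increasing distance-bin edges starting at 0; a final `Inf`
#'   is appended if missing.
#' @return a `data.frame`: `bin, n_tes, mean_sirna_per_bp`.
#' @export
sirna_gene_distance_profile <- function(loci, tes, genes,
                                        breaks = c(0, 1000, 2000, 5000, Inf)) {
  if (is.finite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  d <- nearest_gene_distance(tes, genes)
  gr_t <- .features_granges(tes)
  counts <- if (nrow(loci) == 0L) {
    integer(nrow(tes))
  } else {
    gr_l <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(loci$start + 1L, loci$end))
    GenomicRanges::countOverlaps(gr_t, gr_l)
  }
  dens <- counts / (tes$end - tes$start)
  bin <- cut(d, breaks = breaks, right = FALSE, include.lowest = TRUE)
  res <- data.frame(
    bin = levels(bin),
    n_tes = as.vector(table(bin)),
    mean_sirna_per_bp = as.vector(tapply(dens, bin, mean))[match(levels(bin), levels(bin))],
    stringsAsFactors = FALSE
  )
  res
}
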
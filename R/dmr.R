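#' Default DMR-calling parameters
#'
#' The six region criteria: length 40 bp--10 kb, inter-site gap < 200 bp,
#' per-site coverage >= 10 reads in both tissues (and >= 4 reads at a called
#' methylated cytosine), >= 5 methylated cytosines in at least one tissue,
#' fold change of mean level > 2, and Pearson chi-square p <= 0.05 on the
#' pooled read table. The "more than ten/five" phrasings are resolved
#' inclusively (>= 10, >= 5); both are configurable.
#'
#' @param max_gap maximal allowed distance between adjacent usable sites
#'   minus one (sites chain while the gap is `< max_gap`).
#' @param min_cov per-site read coverage floor, both tissues.
#' @param call_min_cov,call_min_meth methylcytosine call rule (see
#'   [call_modified_sites()]).
#' @param min_len,max_len DMR length bounds in bp.
#' @param min_mc methylated cytosines required in at least one tissue.
#' @param fold_min fold-change bound (strict, `> fold_min`).
#' @param eps pseudocount added to both levels in the fold ratio so that
#'   zero levels stay comparable.
#' @param alpha chi-square significance bound (`p <= alpha`).
#' @return a named list of parameters.
#' @export
dmr_params <- function(max_gap = 200L, min_cov = 10L, call_min_cov = 4L,
                       call_min_meth = 1L, min_len = 40L, max_len = 10000L,
                       min_mc = 5L, fold_min = 2, eps = 0.001, alpha = 0.05) {
  list(max_gap = max_gap, min_cov = min_cov, call_min_cov = call_min_cov,
       call_min_meth = call_min_meth, min_len = min_len, max_len = max_len,
       min_mc = min_mc, fold_min = fold_min, eps = eps, alpha = alpha)
}

# join the two tissues' reports on (chrom, pos, strand) for one context and
# keep "usable" sites: covered >= min_cov in BOTH tissues and called
# methylated in at least one
.usable_sites <- function(sites_A, sites_B, context, params) {
  a <- sites_A[sites_A$context == context, , drop = FALSE]
  b <- sites_B[sites_B$context == context, , drop = FALSE]
  key_a <- paste(a$chrom, a$pos, a$strand)
  key_b <- paste(b$chrom, b$pos, b$strand)
  hit <- match(key_a, key_b)
  keep <- !is.na(hit)
  a <- a[keep, , drop = FALSE]
  bb <- b[hit[keep], , drop = FALSE]
  mod_a <- a$total >= params$call_min_cov & a$meth >= params$call_min_meth
  mod_b <- bb$total >= params$call_min_cov & bb$meth >= params$call_min_meth
  usable <- a$total >= params$min_cov & bb$total >= params$min_cov & (mod_a | mod_b)
  df <- data.frame(chrom = a$chrom[usable], pos = a$pos[usable],
                   meth_A = a$meth[usable], tot_A = a$total[usable],
                   meth_B = bb$meth[usable], tot_B = bb$total[usable],
                   mod_A = mod_a[usable], mod_B = mod_b[usable],
                   stringsAsFactors = FALSE)
  # collapse strands: one record per (chrom, pos); both-strand CG positions
  # stay distinct records in the input, so sum read support per position
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Maximal gap-chained candidate regions
#'
#' Usable sites (covered `>= min_cov` in both tissues and called methylated
#' in at least one) are chained into maximal runs in which successive
#' positions are less than `max_gap` bp apart. Each run is a candidate
#' interval; extending a candidate in either direction would violate the gap
#' rule or usability.
#'
#' @param sites_A,sites_B cytosine reports for the two tissues.
#' @param context one of `CG, CHG, CHH`.
#' @param params a [dmr_params()] list.
#' @return a `data.frame` of candidate intervals (0-based half-open):
#'   `chrom, start, end, n_sites`.
#' @export
candidate_regions <- function(sites_A, sites_B, context, params = dmr_params()) {
  u <- .usable_sites(sites_A, sites_B, context, params)
  if (nrow(u) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  pos_u <- u[!duplicated(paste(u$chrom, u$pos)), c("chrom", "pos")]
  runs <- lapply(split(pos_u$pos, pos_u$chrom), function(p) {
    p <- sort(p)
    grp <- cumsum(c(1L, as.integer(diff(p) >= params$max_gap)))
    data.frame(start = tapply(p, grp, min) - 1L, end = tapply(p, grp, max),
               n_sites = as.integer(tapply(p, grp, length)))
  })
  out <- do.call(rbind, Map(function(cn, r) cbind(chrom = cn, r),
                            names(runs), runs))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(1) region evaluation on prefix sums over one chromosome's usable sites
.region_stats <- function(cs, lo, hi, params) {
  n_sites <- hi - lo + 1L
  start <- cs$pos[lo] - 1L
  end <- cs$pos[hi]
  len <- end - start
  sum_rng <- function(v) v[hi + 1L] - v[lo]
  mc_A <- sum_rng(cs$cmod_A); mc_B <- sum_rng(cs$cmod_B)
  level_A <- sum_rng(cs$clev_A) / n_sites
  level_B <- sum_rng(cs$clev_B) / n_sites
  MA <- sum_rng(cs$cmeth_A); TA <- sum_rng(cs$ctot_A)
  MB <- sum_rng(cs$cmeth_B); TB <- sum_rng(cs$ctot_B)
  reason <- NULL
  chi2 <- NA_real_; p <- NA_real_
  if (len < params$min_len || len > params$max_len) {
    reason <- "length"
  } else if (max(mc_A, mc_B) < params$min_mc) {
    reason <- "methylated_sites"
  } else {
    fold <- (max(level_A, level_B) + params$eps) / (min(level_A, level_B) + params$eps)
    if (fold <= params$fold_min) {
      reason <- "fold_change"
    } else {
      UA <- TA - MA; UB <- TB - MB
      if ((MA + MB) == 0 || (UA + UB) == 0 || TA == 0 || TB == 0) {
        reason <- "degenerate_table"
      } else {
        nn <- TA + TB
        chi2 <- nn * (MA * UB - MB * UA)^2 / (TA * TB * (MA + MB) * (UA + UB))
        p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
        if (p > params$alpha) reason <- "chi_square"
      }
    }
  }
  list(start = start, end = end, n_sites = n_sites, level_A = level_A,
       level_B = level_B,
       fold_change = (max(level_A, level_B) + params$eps) /
         (min(level_A, level_B) + params$eps),
       chi2 = chi2, p = p,
       direction = if (level_A > level_B) "hyper" else "hypo",
       reason = reason, pass = is.null(reason))
}

.prefix_sums <- function(u) {
  list(pos = u$pos,
       cmeth_A = c(0, cumsum(u$meth_A)), ctot_A = c(0, cumsum(u$tot_A)),
       cmeth_B = c(0, cumsum(u$meth_B)), ctot_B = c(0, cumsum(u$tot_B)),
       cmod_A = c(0, cumsum(u$mod_A)), cmod_B = c(0, cumsum(u$mod_B)),
       clev_A = c(0, cumsum(u$meth_A / u$tot_A)),
       clev_B = c(0, cumsum(u$meth_B / u$tot_B)),
       cdiff = c(0, cumsum(u$meth_A / u$tot_A - u$meth_B / u$tot_B)))
}

#' Evaluate one candidate region against the six DMR criteria
#'
#' Applies, in order: the length bounds; the methylated-cytosine count rule
#' (>= `min_mc` in at least one tissue); the fold-change rule on unweighted
#' mean site levels (with pseudocount `eps`); and the Pearson chi-square
#' test (no continuity correction) on the pooled reads 2x2 table. A 2x2
#' table with a zero margin is rejected as `degenerate_table`.
#'
#' @param candidate one row of [candidate_regions()] output.
#' @param sites_A,sites_B cytosine reports for the two tissues.
#' @param context one of `CG, CHG, CHH`.
#' @param params a [dmr_params()] list.
#' @return a list with `pass` (logical), `reason` (`NULL` when passing) and
#'   the region statistics (`level_A, level_B, fold_change, chi2, p,
#'   direction, n_sites`).
#' @export
evaluate_region <- function(candidate, sites_A, sites_B, context,
                            params = dmr_params()) {
  u <- .usable_sites(sites_A, sites_B, context, params)
  u <- u[u$chrom == candidate$chrom &
           u$pos > candidate$start & u$pos <= candidate$end, , drop = FALSE]
  if (nrow(u) == 0L) return(list(pass = FALSE, reason = "no_usable_sites"))
  cs <- .prefix_sums(u)
  .region_stats(cs, 1L, nrow(u), params)
}

# recursive change-point segmentation of a failing run: split at the CUSUM
# argmax of per-site level differences (midpoint when the signal is flat),
# emit passing segments; iterative stack avoids deep recursion
.segment_run <- function(cs, lo, hi, params, out_env) {
  stack <- list(c(lo, hi))
  while (length(stack) > 0L) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- rng[1L]; h <- rng[2L]
    st <- .region_stats(cs, l, h, params)
    if (st$pass) {
      out_env$rows[[length(out_env$rows) + 1L]] <- st
      next
    }
    n <- h - l + 1L
    if (n < 2L || (cs$pos[h] - cs$pos[l] + 1L) < params$min_len) next
    # CUSUM over d_i = level_A - level_B within [l, h]
    k <- seq_len(n - 1L)
    tot <- cs$cdiff[h + 1L] - cs$cdiff[l]
    s_k <- abs((cs$cdiff[l + k] - cs$cdiff[l]) - (k / n) * tot)
    best <- max(s_k)
    cand <- which(s_k >= best - 1e-12)
    split <- cand[which.min(abs(cand - n / 2))]  # balanced among ties
    stack[[length(stack) + 1L]] <- c(l, l + split - 1L)
    stack[[length(stack) + 1L]] <- c(l + split, h)
  }
  invisible(NULL)
}

#' Call differentially methylated regions between two tissues
#'
#' Per context, usable sites are chained into maximal gap-runs
#' ([candidate_regions()]) and each run is evaluated against the six
#' criteria ([evaluate_region()]). With `segment = TRUE` (the default), a
#' failing run is recursively split at the change point of the per-site
#' level differences (CUSUM argmax) and the parts re-evaluated, so that
#' differential intervals embedded in long uniformly methylated runs are
#' still recovered; `segment = FALSE` evaluates only the maximal runs, the
#' literal reading of the region criteria. Segmentation never alters a run
#' that already passes.
#'
#' @param sites_A,sites_B cytosine reports for the two tissues (tissue A is
#'   the reference for the hyper/hypo direction).
#' @param contexts contexts to call (default all three).
#' @param params a [dmr_params()] list.
#' @param segment recursively segment failing candidates (default `TRUE`).
#' @param adjust `"none"` (the criteria use raw p <= alpha) or `"BH"` to
#'   additionally require a Benjamini-Hochberg adjusted p <= alpha across
#'   all evaluated candidates of a context.
#' @return a `data.frame` of DMRs (0-based half-open): `chrom, start, end,
#'   context, n_sites, level_A, level_B, fold_change, chi2, p, direction`.
#' @export
call_dmrs <- function(sites_A, sites_B, contexts = c("CG", "CHG", "CHH"),
                      params = dmr_params(), segment = TRUE,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  all_rows <- list()
  for (cx in contexts) {
    u_all <- .usable_sites(sites_A, sites_B, cx, params)
    if (nrow(u_all) == 0L) next
    for (cn in unique(u_all$chrom)) {
      u <- u_all[u_all$chrom == cn, , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(diff(u$pos) >= params$max_gap)))
      # positions can repeat (both strands); gaps computed on position diffs
      for (g in unique(grp)) {
        idx <- which(grp == g)
        ui <- u[idx, , drop = FALSE]
        cs <- .prefix_sums(ui)
        env <- new.env()
        env$rows <- list()
        st <- .region_stats(cs, 1L, nrow(ui), params)
        if (st$pass) {
          env$rows[[1L]] <- st
        } else if (segment) {
          .segment_run(cs, 1L, nrow(ui), params, env)
        }
        for (r in env$rows) {
          all_rows[[length(all_rows) + 1L]] <- data.frame(
            chrom = cn, start = r$start, end = r$end, context = cx,
            n_sites = r$n_sites, level_A = r$level_A, level_B = r$level_B,
            fold_change = r$fold_change, chi2 = r$chi2, p = r$p,
            direction = r$direction, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(all_rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      context = character(), n_sites = integer(),
                      level_A = numeric(), level_B = numeric(),
                      fold_change = numeric(), chi2 = numeric(), p = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, all_rows)
  if (adjust == "BH") {
    out <- do.call(rbind, lapply(split(out, out$context), function(d) {
      d[p.adjust(d$p, "BH") <= params$alpha, , drop = FALSE]
    }))
  }
  out <- out[order(out$context, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize called DMRs
#'
#' @param dmrs output of [call_dmrs()].
#' @return a `data.frame` per context: `context, n, n_hyper, n_hypo,
#'   pct_hyper` (`NA` when a context has no DMRs).
#' @export
summarize_dmrs <- function(dmrs) {
  res <- lapply(.contexts, function(cx) {
    d <- dmrs[dmrs$context == cx, , drop = FALSE]
    n_hyper <- sum(d$direction == "hyper")
    data.frame(context = cx, n = nrow(d), n_hyper = n_hyper,
               n_hypo = nrow(d) - n_hyper,
               pct_hyper = if (nrow(d) == 0L) NA_real_ else 100 * n_hyper / nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Map DMRs to gene regions
#'
#' Emits one triple for every (gene, region) whose interval overlaps a DMR
#' by at least 1 bp; regions are the gene-oriented 2-kb upstream flank, the
#' body, and the 2-kb downstream flank. A DMR may hit several genes and
#' several regions of the same gene.
#'
#' @param dmrs output of [call_dmrs()].
#' @param genes gene features.
#' @param flank_bp flank width (default 2000).
#' @return a `data.frame`: `gene, region, dmr_chrom, dmr_start, dmr_end,
#'   context, direction`.
#' @export
assign_dmr_to_genes <- function(dmrs, genes, flank_bp = 2000L) {
  empty <- data.frame(gene = character(), region = character(),
                      dmr_chrom = character(), dmr_start = integer(),
                      dmr_end = integer(), context = character(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(empty)
  plus <- genes$strand == "+"
  regions <- rbind(
    data.frame(gene = genes$id, region = "upstream", chrom = genes$chrom,
               start = ifelse(plus, pmax(0L, genes$start - flank_bp), genes$end),
               end = ifelse(plus, genes$start, genes$end + flank_bp)),
    data.frame(gene = genes$id, region = "body", chrom = genes$chrom,
               start = genes$start, end = genes$end),
    data.frame(gene = genes$id, region = "downstream", chrom = genes$chrom,
               start = ifelse(plus, genes$end, pmax(0L, genes$start - flank_bp)),
               end = ifelse(plus, genes$end + flank_bp, genes$start))
  )
  regions <- regions[regions$end > regions$start, , drop = FALSE]
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L, regions$end))
  gr_dmr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_dmr)
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- data.frame(gene = regions$gene[qi], region = regions$region[qi],
                    dmr_chrom = dmrs$chrom[si], dmr_start = dmrs$start[si],
                    dmr_end = dmrs$end[si], context = dmrs$context[si],
                    direction = dmrs$direction[si], stringsAsFactors = FALSE)
  out[order(out$gene, out$region, out$dmr_start), , drop = FALSE]
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric test per term (probability of an overlap at
#' least as large as observed between the hit set and the term's gene set,
#' drawn from the universe), Benjamini-Hochberg adjustment across terms,
#' and flagging at adjusted p <= `alpha`.
#'
#' @param hit_genes character vector of hit gene ids (subset of universe).
#' @param universe_genes character vector, the sampling universe.
#' @param term_to_genes named list mapping term ids to gene-id vectors
#'   (each a subset of the universe).
#' @param alpha significance bound on the adjusted p (default 0.05).
#' @return a `data.frame`: `term, n_term, n_hits, overlap, p, p_adj,
#'   enriched`, ordered by p.
#' @export
term_enrichment <- function(hit_genes, universe_genes, term_to_genes,
                            alpha = 0.05) {
  if (length(universe_genes) == 0L) .stopf("empty gene universe")
  if (!all(hit_genes %in% universe_genes)) .stopf("hits outside the universe")
  N <- length(unique(universe_genes))
  hits <- unique(hit_genes)
  n <- length(hits)
  res <- lapply(names(term_to_genes), function(tm) {
    tg <- intersect(unique(term_to_genes[[tm]]), universe_genes)
    K <- length(tg)
    k <- length(intersect(tg, hits))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_term = K, n_hits = n, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj <= alpha
  out[order(out$p), , drop = FALSE]
}
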
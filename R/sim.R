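#' Simulation configuration for a two-tissue methylome study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate a
#' leaf/root bisulfite experiment in a heavily methylated grass genome:
#' context base levels CG 0.60, CHG 0.40, CHH 0.04 in tissue A (leaf) with
#' CHH raised to 0.07 in tissue B (root); transposable-element bodies
#' hypermethylated by an additive boost; metagene-shaped modulation around
#' genes at 100-bp resolution; ~25x Poisson read coverage per cytosine; and
#' 20 planted CG DMRs (level 0.8 vs 0.2, 500 bp) with a recorded truth set.
#'
#' @param seed integer master seed; every stage derives its own sub-seed so
#'   adding a stage never perturbs earlier stages' draws.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param gc_fraction genome GC content in `[0, 1]`.
#' @param n_genes,n_tes,n_lncrnas feature counts for the whole genome.
#' @param base_levels per-tissue named context methylation probabilities,
#'   a list with elements `A` and `B`.
#' @param te_level_boost additive level increase inside TE bodies.
#' @param metagene_shape per-context multipliers `flank`, `tss_dip`, `body`;
#'   the dip applies to the 200 bp centred on the TSS.
#' @param coverage_mean expected reads per cytosine (Poisson).
#' @param planted_dmrs `data.frame` with columns `context, length, level_A,
#'   level_B`; one row per DMR to plant (lengths 40--10000 bp).
#' @param hurdle_params generative expression model: list with `zero`
#'   (logistic intercept + upstream/body/downstream slopes for the
#'   probability of being expressed), `count` (log-link intercept + slopes of
#'   the zero-truncated negative binomial), `dispersion` (NB size theta) and
#'   `context` (which context's methylated-cytosine counts act as
#'   covariates).
#' @param library_size fixed library size used to derive RPKM from counts.
#' @param gene_length_range,te_length_range,lncrna_length_range sampled
#'   feature lengths in bp.
#' @param sirna_intensity expected 24-nt siRNA loci per kb in a TE
#'   overlapping a gene; decays with TE-to-gene distance.
#' @param sirna_decay_bp exponential decay scale of siRNA intensity with
#'   distance to the nearest gene.
#' @param contexts contexts to emit in simulated reports (restricting to one
#'   context speeds up large parameter-recovery runs).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 200000L,
                       gc_fraction = 0.45,
                       n_genes = 20L, n_tes = 15L, n_lncrnas = 12L,
                       base_levels = list(
                         A = c(CG = 0.60, CHG = 0.40, CHH = 0.04),
                         B = c(CG = 0.60, CHG = 0.40, CHH = 0.07)
                       ),
                       te_level_boost = 0.15,
                       metagene_shape = list(
                         CG  = c(flank = 1.0, tss_dip = 0.5, body = 1.1),
                         CHG = c(flank = 1.0, tss_dip = 0.5, body = 1.0),
                         CHH = c(flank = 1.2, tss_dip = 0.8, body = 0.8)
                       ),
                       coverage_mean = 25,
                       planted_dmrs = data.frame(
                         context = "CG", length = 500L,
                         level_A = 0.8, level_B = 0.2
                       )[rep(1L, 20L), , drop = FALSE],
                       hurdle_params = list(
                         zero  = c(intercept = 1.0, upstream = -0.005,
                                   body = 0.010, downstream = -0.005),
                         count = c(intercept = 3.0, upstream = -0.004,
                                   body = 0.012, downstream = -0.004),
                         dispersion = 1.5, context = "CG"
                       ),
                       library_size = 1e6,
                       gene_length_range = c(1200L, 3000L),
                       te_length_range = c(500L, 2500L),
                       lncrna_length_range = c(200L, 800L),
                       sirna_intensity = 5,
                       sirna_decay_bp = 2000,
                       contexts = c("CG", "CHG", "CHH")) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              n_tes = as.integer(n_tes), n_lncrnas = as.integer(n_lncrnas),
              base_levels = base_levels, te_level_boost = te_level_boost,
              metagene_shape = metagene_shape, coverage_mean = coverage_mean,
              planted_dmrs = planted_dmrs, hurdle_params = hurdle_params,
              library_size = library_size,
              gene_length_range = gene_length_range,
              te_length_range = te_length_range,
              lncrna_length_range = lncrna_length_range,
              sirna_intensity = sirna_intensity, sirna_decay_bp = sirna_decay_bp,
              contexts = contexts)
  probs <- unlist(base_levels)
  if (any(probs < 0 | probs > 1)) .stopf("base levels must lie in [0, 1]")
  if (gc_fraction < 0 || gc_fraction > 1) .stopf("gc_fraction must lie in [0, 1]")
  if (coverage_mean <= 0) .stopf("coverage_mean must be positive")
  if (nrow(planted_dmrs) > 0 &&
      (any(planted_dmrs$length < 40) || any(planted_dmrs$length > 10000)))
    .stopf("planted DMR lengths must lie in [40, 10000] bp")
  class(cfg) <- "sim_config"
  cfg
}

# keyed sub-stream per stage: stages draw from disjoint seeds so adding a
# stage never changes earlier stages' output
.stage_seed <- function(seed, stage) {
  k <- match(stage, c("genome", "annotation", "methylome", "expression", "sirna"))
  as.integer((as.numeric(seed) + k * 1000003) %% .Machine$integer.max)
}

#' Simulate a genome
#'
#' Independent bases with `P(G) = P(C) = gc_fraction / 2`. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return a named `Biostrings::DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
make_genome <- function(config) {
  set.seed(.stage_seed(config$seed, "genome"))
  gc <- config$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(names(p), config$chromosome_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
  Biostrings::DNAStringSet(seqs)
}

# --- free-interval bookkeeping for feature placement -------------------------

.free_new <- function(chroms, lengths) {
  data.frame(chrom = chroms, start = 0L, end = as.integer(lengths),
             stringsAsFactors = FALSE)
}

# reserve [start - margin, start + len + margin) from the free set and return
# the chosen placement; NULL when nothing fits
.free_take <- function(free, len, margin, chrom = NULL) {
  need <- len + 2L * margin
  cand <- which((free$end - free$start) >= need &
                  (is.null(chrom) | free$chrom == (chrom %||% "")))
  if (length(cand) == 0L) return(NULL)
  w <- (free$end - free$start)[cand]
  row <- cand[sample.int(length(cand), 1L, prob = w)]
  lo <- free$start[row] + margin
  hi <- free$end[row] - margin - len
  s <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
  placed <- list(chrom = free$chrom[row], start = s, end = s + len)
  left <- free[row, ]; left$end <- s - margin
  right <- free[row, ]; right$start <- s + len + margin
  keep <- free[-row, , drop = FALSE]
  for (piece in list(left, right)) {
    if (piece$end - piece$start > 0L) keep <- rbind(keep, piece)
  }
  placed$free <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  placed
}

# equal-partition exon structure: 2k-1 alternating blocks, exons at odd blocks
.make_exons <- function(start, end, n_exons) {
  if (n_exons <= 1L) return(cbind(start = start, end = end))
  nb <- 2L * n_exons - 1L
  bounds <- round(seq(start, end, length.out = nb + 1L))
  odd <- seq(1L, nb, by = 2L)
  cbind(start = as.integer(bounds[odd]), end = as.integer(bounds[odd + 1L]))
}

#' Simulate gene, TE and lncRNA annotation with a truth skeleton
#'
#' Genes (1--5 exons) are placed without overlap and with at least 2 kb
#' spacing; TEs draw uniformly from the ten canonical families; lncRNAs are
#' laid out so that, with `n_lncrnas >= 12`, all six positional classes
#' (sense, intronic sense, antisense, intronic antisense, bidirectional,
#' intergenic) occur, and the intended class of each is recorded in the truth
#' set. Planted DMR intervals are reserved in intergenic space at least 1 kb
#' apart.
#'
#' @param genome from [make_genome()].
#' @param config the same [sim_config()].
#' @return a list with `features` (a [feature_table()]) and `truth` (list
#'   with `lncrna_classes` and `dmrs`).
#' @export
make_annotation <- function(genome, config) {
  set.seed(.stage_seed(config$seed, "annotation"))
  chroms <- names(genome)
  lens <- setNames(Biostrings::width(genome), chroms)
  free <- .free_new(chroms, lens)
  rows <- list()
  add_row <- function(id, chrom, start, end, strand, kind,
                      te_family = NA_character_, exons = NULL) {
    rows[[length(rows) + 1L]] <<- list(id = id, chrom = chrom, start = start,
                                       end = end, strand = strand, kind = kind,
                                       te_family = te_family, exons = exons)
  }

  # genes -- margin 2000 keeps bodies >= 2 kb apart and leaves flank room
  gene_meta <- list()
  for (i in seq_len(config$n_genes)) {
    len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
    pl <- .free_take(free, len, margin = 2000L)
    if (is.null(pl)) .stopf("genome too small for %d genes", config$n_genes)
    free <- pl$free
    strand <- sample(c("+", "-"), 1L)
    ne <- sample(1:5, 1L)
    id <- sprintf("gene%03d", i)
    add_row(id, pl$chrom, pl$start, pl$end, strand, "gene",
            exons = .make_exons(pl$start, pl$end, ne))
    gene_meta[[i]] <- list(id = id, chrom = pl$chrom, start = pl$start,
                           end = pl$end, strand = strand, n_exons = ne)
  }

  # TEs: a third sit right in gene upstream flanks (where RdDM concentrates
  # 24-nt siRNAs), the rest in remaining intergenic space
  fams <- unlist(.te_families, use.names = FALSE)
  for (i in seq_len(config$n_tes)) {
    len <- sample(config$te_length_range[1]:config$te_length_range[2], 1L)
    near_gene <- config$n_genes > 0L && i %% 3L == 0L
    if (near_gene) {
      g <- gene_meta[[(i %/% 3L - 1L) %% length(gene_meta) + 1L]]
      gap <- sample(50:800, 1L)
      if (g$strand == "+") {
        e <- g$start - gap
        s <- e - len
      } else {
        s <- g$end + gap
        e <- s + len
      }
      if (s >= 0L && e <= lens[[g$chrom]]) {
        add_row(sprintf("te%03d", i), g$chrom, s, e,
                sample(c("+", "-"), 1L), "TE", te_family = sample(fams, 1L))
        next
      }
    }
    len <- min(len, 2000L)
    pl <- .free_take(free, len, margin = 100L)
    if (is.null(pl)) .stopf("genome too small for %d TEs", config$n_tes)
    free <- pl$free
    add_row(sprintf("te%03d", i), pl$chrom, pl$start, pl$end,
            sample(c("+", "-"), 1L), "TE", te_family = sample(fams, 1L))
  }

  # lncRNAs cycle the six positional classes, anchored round-robin to genes
  classes <- c("sense", "intronic sense", "antisense", "intronic antisense",
               "bidirectional", "intergenic")
  multi_exon <- which(vapply(gene_meta, function(g) g$n_exons >= 2L, TRUE))
  lnc_truth <- list()
  gi <- 0L
  for (i in seq_len(config$n_lncrnas)) {
    cls <- classes[(i - 1L) %% 6L + 1L]
    len <- sample(config$lncrna_length_range[1]:config$lncrna_length_range[2], 1L)
    id <- sprintf("lnc%03d", i)
    if (cls %in% c("intronic sense", "intronic antisense")) {
      if (length(multi_exon) == 0L) .stopf("need a multi-exon gene for intronic lncRNAs")
      gi <- gi + 1L
      g <- gene_meta[[multi_exon[(gi - 1L) %% length(multi_exon) + 1L]]]
      ex <- .make_exons(g$start, g$end, g$n_exons)
      intron <- c(ex[1L, "end"], ex[2L, "start"])  # first intron
      ilen <- min(len, intron[2L] - intron[1L] - 2L)
      if (ilen < 50L) .stopf("intron too short for lncRNA placement")
      s <- intron[1L] + 1L
      strand <- if (cls == "intronic sense") g$strand else setdiff(c("+", "-"), g$strand)
      add_row(id, g$chrom, s, s + ilen, strand, "lncRNA",
              exons = cbind(start = s, end = s + ilen))
      anchor <- g$id
    } else if (cls %in% c("sense", "antisense")) {
      gi <- gi + 1L
      g <- gene_meta[[(gi - 1L) %% length(gene_meta) + 1L]]
      ex <- .make_exons(g$start, g$end, g$n_exons)
      s <- ex[1L, "start"] + 5L  # overlaps exonic bp of the anchor gene
      e <- min(s + len, g$end)
      strand <- if (cls == "sense") g$strand else setdiff(c("+", "-"), g$strand)
      add_row(id, g$chrom, s, e, strand, "lncRNA", exons = cbind(start = s, end = e))
      anchor <- g$id
    } else if (cls == "bidirectional") {
      gi <- gi + 1L
      g <- gene_meta[[(gi - 1L) %% length(gene_meta) + 1L]]
      gap <- 300L
      if (g$strand == "+") {        # divergent partner points left of the TSS
        e <- g$start - gap
        s <- max(0L, e - len)
        strand <- "-"
      } else {                      # TSS at the right end; partner points right
        s <- g$end + gap
        e <- s + len
        strand <- "+"
      }
      add_row(id, g$chrom, s, e, strand, "lncRNA", exons = cbind(start = s, end = e))
      anchor <- g$id
    } else {                        # intergenic: > 1 kb from any gene or TSS
      pl <- .free_take(free, len, margin = 1200L)
      if (is.null(pl)) .stopf("genome too small for intergenic lncRNAs")
      free <- pl$free
      add_row(id, pl$chrom, pl$start, pl$end, sample(c("+", "-"), 1L), "lncRNA",
              exons = cbind(start = pl$start, end = pl$end))
      anchor <- NA_character_
    }
    lnc_truth[[i]] <- data.frame(id = id, class = cls, anchor = anchor,
                                 stringsAsFactors = FALSE)
  }

  # planted DMR intervals in intergenic space, >= 1 kb apart
  dmr_truth <- NULL
  pd <- config$planted_dmrs
  if (!is.null(pd) && nrow(pd) > 0L) {
    recs <- vector("list", nrow(pd))
    for (i in seq_len(nrow(pd))) {
      pl <- .free_take(free, as.integer(pd$length[i]), margin = 600L)
      if (is.null(pl)) .stopf("genome too small for %d planted DMRs", nrow(pd))
      free <- pl$free
      recs[[i]] <- data.frame(
        chrom = pl$chrom, start = pl$start, end = pl$end,
        context = pd$context[i], level_A = pd$level_A[i], level_B = pd$level_B[i],
        direction = ifelse(pd$level_A[i] > pd$level_B[i], "hyper", "hypo"),
        stringsAsFactors = FALSE
      )
    }
    dmr_truth <- do.call(rbind, recs)
  }

  features <- feature_table(
    id = vapply(rows, `[[`, "", "id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    kind = vapply(rows, `[[`, "", "kind"),
    te_family = vapply(rows, `[[`, "", "te_family"),
    exons = lapply(rows, `[[`, "exons")
  )
  list(features = features,
       truth = list(lncrna_classes = do.call(rbind, lnc_truth), dmrs = dmr_truth))
}

# per-position context multiplier and TE boost vectors for one chromosome
.level_tracks <- function(L, features_chr, shape, te_boost) {
  mult <- setNames(lapply(.contexts, function(cx) rep(1, L)), .contexts)
  boost <- numeric(L)
  clamp <- function(i) i[i >= 1L & i <= L]
  genes <- features_chr[features_chr$kind == "gene", , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    body <- clamp((g$start + 1L):g$end)
    up <- if (g$strand == "+") clamp((g$start - 1999L):g$start) else clamp((g$end + 1L):(g$end + 2000L))
    dn <- if (g$strand == "+") clamp((g$end + 1L):(g$end + 2000L)) else clamp((g$start - 1999L):g$start)
    tss <- if (g$strand == "+") g$start + 1L else g$end
    dip <- clamp((tss - 100L):(tss + 99L))
    for (cx in .contexts) {
      sh <- shape[[cx]]
      mult[[cx]][up] <- sh[["flank"]]
      mult[[cx]][dn] <- sh[["flank"]]
      mult[[cx]][body] <- sh[["body"]]
      mult[[cx]][dip] <- sh[["tss_dip"]]
    }
  }
  tes <- features_chr[features_chr$kind == "TE", , drop = FALSE]
  for (i in seq_len(nrow(tes))) {
    boost[clamp((tes$start[i] + 1L):tes$end[i])] <- te_boost
  }
  list(mult = mult, boost = boost)
}

#' Simulate two-tissue per-cytosine methylation reports
#'
#' Every genomic cytosine (of the configured contexts) receives an intended
#' methylation level `clip(base_level x metagene multiplier + TE boost, 0,
#' 1)`; inside planted DMR intervals the two tissues' levels are overridden
#' by the planted `level_A` / `level_B`. Read coverage is Poisson per site
#' and independent between tissues; sites with zero simulated coverage are
#' omitted; methylated read counts are Binomial(coverage, level).
#'
#' @param genome from [make_genome()].
#' @param features annotation [feature_table()].
#' @param config the [sim_config()].
#' @param dmr_truth planted DMR intervals (`truth$dmrs` from
#'   [make_annotation()]); `NULL` plants nothing.
#' @return a list with cytosine reports `A` and `B`.
#' @export
simulate_methylomes <- function(genome, features, config, dmr_truth = NULL) {
  set.seed(.stage_seed(config$seed, "methylome"))
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (!is.null(dmr_truth) && nrow(dmr_truth) > 0L) {
    if (any(!(dmr_truth$chrom %in% names(lens))) ||
        any(dmr_truth$end > lens[dmr_truth$chrom]))
      .stopf("planted DMR outside the simulated genome")
  }
  ctx <- cytosine_contexts(genome, contexts = config$contexts)

  level_A <- numeric(nrow(ctx))
  level_B <- numeric(nrow(ctx))
  for (cn in names(lens)) {
    sel <- which(ctx$chrom == cn)
    if (length(sel) == 0L) next
    tracks <- .level_tracks(lens[[cn]],
                            features[features$chrom == cn, , drop = FALSE],
                            config$metagene_shape, config$te_level_boost)
    pos <- ctx$pos[sel]
    m <- numeric(length(sel))
    for (cx in .contexts) {
      in_cx <- ctx$context[sel] == cx
      if (!any(in_cx)) next
      mu <- tracks$mult[[cx]][pos[in_cx]]
      level_A[sel[in_cx]] <- pmin(1, pmax(0,
        config$base_levels$A[[cx]] * mu + tracks$boost[pos[in_cx]]))
      level_B[sel[in_cx]] <- pmin(1, pmax(0,
        config$base_levels$B[[cx]] * mu + tracks$boost[pos[in_cx]]))
    }
  }
  if (!is.null(dmr_truth) && nrow(dmr_truth) > 0L) {
    for (i in seq_len(nrow(dmr_truth))) {
      d <- dmr_truth[i, ]
      hit <- ctx$chrom == d$chrom & ctx$context == d$context &
        ctx$pos > d$start & ctx$pos <= d$end
      level_A[hit] <- d$level_A
      level_B[hit] <- d$level_B
    }
  }

  draw <- function(level) {
    cov <- rpois(nrow(ctx), config$coverage_mean)
    keep <- cov >= 1L
    meth <- integer(nrow(ctx))
    meth[keep] <- rbinom(sum(keep), cov[keep], level[keep])
    df <- data.frame(chrom = ctx$chrom[keep], pos = ctx$pos[keep],
                     strand = ctx$strand[keep], context = ctx$context[keep],
                     meth = meth[keep], total = cov[keep], tri = ctx$tri[keep],
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  }
  list(A = draw(level_A), B = draw(level_B))
}

#' Simulate expression from a hurdle model on methylation covariates
#'
#' Per-gene covariates are the counts of called methylated cytosines in the
#' 2-kb upstream flank, gene body and 2-kb downstream flank (gene-oriented)
#' for the configured context. Expressed / silent status is Bernoulli with
#' logistic probability on the zero-part coefficients; positive counts come
#' from a zero-truncated negative binomial with log link on the count-part
#' coefficients; RPKM derives from counts, gene length and the fixed library
#' size.
#'
#' @param genes gene rows of the annotation.
#' @param report the tissue's cytosine report.
#' @param config the [sim_config()].
#' @return a list with `expression` (`id, count, rpkm`), `covariates`
#'   (matrix with columns upstream/body/downstream) and `truth` (the
#'   generative coefficients).
#' @export
simulate_expression <- function(genes, report, config) {
  set.seed(.stage_seed(config$seed, "expression"))
  hp <- config$hurdle_params
  sites <- call_modified_sites(report)
  X <- methylation_covariates(sites, genes, context = hp$context)
  eta_zero <- hp$zero[["intercept"]] +
    as.vector(X %*% hp$zero[c("upstream", "body", "downstream")])
  p_pos <- plogis(eta_zero)
  expressed <- rbinom(nrow(X), 1L, p_pos) == 1L
  mu <- exp(hp$count[["intercept"]] +
              as.vector(X %*% hp$count[c("upstream", "body", "downstream")]))
  y <- integer(nrow(X))
  if (any(expressed)) {
    p0 <- dnbinom(0, size = hp$dispersion, mu = mu[expressed])
    u <- runif(sum(expressed), min = p0, max = 1)
    y[expressed] <- pmax(1L, qnbinom(u, size = hp$dispersion, mu = mu[expressed]))
  }
  len_kb <- (genes$end - genes$start) / 1000
  rpkm <- y / (len_kb * (config$library_size / 1e6))
  list(
    expression = data.frame(id = genes$id, count = y, rpkm = rpkm,
                            stringsAsFactors = FALSE),
    covariates = X,
    truth = hp
  )
}

#' Simulate 24-nt siRNA loci
#'
#' Loci are 24 bp and placed with Poisson intensity that is highest in TEs
#' overlapping genes and decays exponentially with the TE's distance to its
#' nearest gene; gene 2-kb upstream flanks (where CHH methylation is
#' elevated) receive a reduced background intensity. Mirrors the
#' RNA-directed DNA methylation geography the classifier and association
#' statistics are meant to detect.
#'
#' @param features annotation table (genes and TEs used).
#' @param config the [sim_config()].
#' @return a BED-like `data.frame` (`chrom, start, end, name, score,
#'   strand`), 0-based half-open, each locus 24 bp.
#' @export
simulate_sirna <- function(features, config) {
  set.seed(.stage_seed(config$seed, "sirna"))
  tes <- features[features$kind == "TE", , drop = FALSE]
  genes <- features[features$kind == "gene", , drop = FALSE]
  rate_kb <- config$sirna_intensity
  out <- list()
  emit <- function(chrom, lo, hi, n, tag) {
    if (n <= 0L || hi - lo < 24L) return(NULL)
    s <- lo + sample.int(hi - lo - 23L, n, replace = TRUE) - 1L
    data.frame(chrom = chrom, start = s, end = s + 24L,
               name = sprintf("%s_s%d", tag, seq_len(n)), score = 0,
               strand = ".", stringsAsFactors = FALSE)
  }
  if (rate_kb > 0 && nrow(tes) > 0L) {
    d <- nearest_gene_distance(tes, genes)
    lam <- rate_kb / 1000 * exp(-ifelse(is.na(d), Inf, d) / config$sirna_decay_bp) *
      (tes$end - tes$start)
    n_loci <- rpois(nrow(tes), lam)
    for (i in seq_len(nrow(tes))) {
      out[[length(out) + 1L]] <- emit(tes$chrom[i], tes$start[i], tes$end[i],
                                      n_loci[i], tes$id[i])
    }
    # RdDM background over gene upstream flanks
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      up <- if (g$strand == "+") c(max(0L, g$start - 2000L), g$start)
            else c(g$end, g$end + 2000L)
      n_up <- rpois(1L, 0.3 * rate_kb / 1000 * (up[2L] - up[1L]))
      out[[length(out) + 1L]] <- emit(g$chrom, up[1L], up[2L], n_up,
                                      paste0(g$id, "_up"))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full simulation pipeline
#'
#' Genome, annotation, two-tissue methylomes with planted DMRs, hurdle-model
#' expression for tissue A, and siRNA loci, with the complete truth set.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list: `genome`, `features`, `report_A`, `report_B`,
#'   `expression`, `covariates`, `sirna`, `truth` (with `dmrs`,
#'   `lncrna_classes`, `hurdle`), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- make_genome(config)
  ann <- make_annotation(genome, config)
  meth <- simulate_methylomes(genome, ann$features, config, ann$truth$dmrs)
  genes <- ann$features[ann$features$kind == "gene", , drop = FALSE]
  expr <- simulate_expression(genes, meth$A, config)
  sirna <- simulate_sirna(ann$features, config)
  list(genome = genome, features = ann$features,
       report_A = meth$A, report_B = meth$B,
       expression = expr$expression, covariates = expr$covariates,
       sirna = sirna,
       truth = list(dmrs = ann$truth$dmrs,
                    lncrna_classes = ann$truth$lncrna_classes,
                    hurdle = expr$truth),
       config = config)
}

#' Write a simulated study to a directory
#'
#' Genome as FASTA, annotation as GFF3, the two cytosine reports as TSV,
#' expression as TSV, siRNA loci as BED6 and the truth tables as TSV.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_features_gff3(sim$features, file.path(dir, "features.gff3"))
  write_cytosine_report(sim$report_A, file.path(dir, "tissueA.cx.tsv"))
  write_cytosine_report(sim$report_B, file.path(dir, "tissueB.cx.tsv"))
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  write_bed_loci(sim$sirna, file.path(dir, "sirna.bed"))
  if (!is.null(sim$truth$dmrs))
    write.table(sim$truth$dmrs, file.path(dir, "truth_dmrs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$lncrna_classes, file.path(dir, "truth_lncrna.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
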
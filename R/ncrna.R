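#' Positional classification of lncRNAs relative to protein-coding genes
#'
#' Assigns each lncRNA exactly one of six positional classes, testing rules
#' in a fixed precedence order (first match wins):
#'
#' 1. **sense** -- overlaps at least 1 exonic bp of a same-strand gene;
#' 2. **intronic sense** -- fully inside an intron of a same-strand gene;
#' 3. **antisense** -- overlaps at least 1 exonic bp of an opposite-strand
#'    gene;
#' 4. **intronic antisense** -- fully inside an intron of an opposite-strand
#'    gene;
#' 5. **bidirectional** -- overlaps no gene, and its 5' end lies within
#'    `bidirectional_window` bp of a gene's TSS with divergent
#'    (head-to-head) orientation;
#' 6. **intergenic** -- otherwise.
#'
#' The anchor is the gene that triggers the matched rule (nearest qualifying
#' gene on ties, then lexicographically smallest id); intergenic lncRNAs
#' have no anchor.
#'
#' @param lncrnas lncRNA features (strand required).
#' @param genes gene features with exon structure.
#' @param bidirectional_window distance bound for the divergent-promoter
#'   rule (default 1000 bp, the usual divergent-transcription convention).
#' @return a `data.frame`: `id, class, anchor, distance` (gap to the anchor
#'   gene in bp, 0 when overlapping; `NA` for intergenic).
#' @export
classify_lncrna <- function(lncrnas, genes, bidirectional_window = 1000L) {
  if (any(!lncrnas$strand %in% c("+", "-"))) .stopf("lncRNA lacking strand")
  gene_exons <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (is.null(ex)) cbind(start = genes$start[i], end = genes$end[i]) else ex
  })
  gene_introns <- lapply(gene_exons, function(ex) {
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    cbind(start = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
  })
  gap <- function(s1, e1, s2, e2) {
    if (e1 > s2 && e2 > s1) 0L else max(s2 - e1, s1 - e2)
  }
  out <- vector("list", nrow(lncrnas))
  for (i in seq_len(nrow(lncrnas))) {
    l <- lncrnas[i, ]
    gsel <- which(genes$chrom == l$chrom)
    cls <- "intergenic"; anchor <- NA_character_; dist <- NA_integer_
    pick <- function(cand) {
      # nearest qualifying gene, ties broken lexicographically
      d <- vapply(cand, function(g) gap(l$start, l$end, genes$start[g], genes$end[g]), 0L)
      o <- order(d, genes$id[cand])
      c(cand[o[1L]], d[o[1L]])
    }
    rules <- list(
      sense = function(g) genes$strand[g] == l$strand &&
        any(gene_exons[[g]][, 2L] > l$start & gene_exons[[g]][, 1L] < l$end),
      `intronic sense` = function(g) genes$strand[g] == l$strand &&
        !is.null(gene_introns[[g]]) &&
        any(gene_introns[[g]][, 1L] <= l$start & gene_introns[[g]][, 2L] >= l$end),
      antisense = function(g) genes$strand[g] != l$strand &&
        any(gene_exons[[g]][, 2L] > l$start & gene_exons[[g]][, 1L] < l$end),
      `intronic antisense` = function(g) genes$strand[g] != l$strand &&
        !is.null(gene_introns[[g]]) &&
        any(gene_introns[[g]][, 1L] <= l$start & gene_introns[[g]][, 2L] >= l$end),
      bidirectional = function(g) {
        if (genes$strand[g] == l$strand) return(FALSE)
        # no overlap with any gene at all (checked once outside)
        if (genes$strand[g] == "+") {
          l$strand == "-" && l$end <= genes$start[g] &&
            genes$start[g] - l$end <= bidirectional_window
        } else {
          l$strand == "+" && l$start >= genes$end[g] &&
            l$start - genes$end[g] <= bidirectional_window
        }
      }
    )
    overlaps_any_gene <- any(genes$start[gsel] < l$end & genes$end[gsel] > l$start)
    for (rule in names(rules)) {
      if (rule == "bidirectional" && overlaps_any_gene) next
      cand <- gsel[vapply(gsel, rules[[rule]], TRUE)]
      if (length(cand) > 0L) {
        hit <- pick(cand)
        cls <- rule; anchor <- genes$id[hit[1L]]; dist <- hit[2L]
        break
      }
    }
    out[[i]] <- data.frame(id = l$id, class = cls, anchor = anchor,
                           distance = dist, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distance to the nearest gene
#'
#' Gap in bp between each feature and its closest gene on the same
#' chromosome (0 when overlapping or directly adjacent); `NA` for features
#' on gene-free chromosomes.
#'
#' @param features feature table.
#' @param genes gene features.
#' @return numeric vector, one distance per feature row.
#' @export
nearest_gene_distance <- function(features, genes) {
  if (nrow(features) == 0L) return(numeric(0))
  if (nrow(genes) == 0L) return(rep(NA_real_, nrow(features)))
  gr_f <- .features_granges(features)
  gr_g <- .features_granges(genes)
  # differing chromosome sets are expected (features on gene-free
  # chromosomes get NA), so the seqlevel warning is silenced
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(gr_f, gr_g, ignore.strand = TRUE)
  )
  d <- rep(NA_real_, nrow(features))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Retain 24-nt siRNA reads
#'
#' The retention rule for small-RNA reads entering siRNA analyses: keep
#' exactly the reads of length 24 nt that carry no exclusion annotation
#' (miRNA, rRNA, snRNA, snoRNA, scRNA, tRNA, exon, intron).
#'
#' @param reads a `data.frame` with columns `sequence` (optional), `length`
#'   and `flag` (`NA` or empty when unannotated).
#' @return the retained subset of `reads`.
#' @export
filter_sirna_reads <- function(reads) {
  if (!is.null(reads$sequence)) {
    n <- nchar(reads$sequence)
    if (any(n != reads$length)) .stopf("length column disagrees with sequence")
  }
  if (any(reads$length < 18L | reads$length > 30L))
    .stopf("read length outside the 18-30 nt input range")
  keep <- reads$length == 24L & (is.na(reads$flag) | reads$flag == "")
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
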
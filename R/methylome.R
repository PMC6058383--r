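#' Classify the sequence context of a cytosine
#'
#' Returns `"CG"`, `"CHG"` or `"CHH"` (H = A, T or C) for the cytosine at
#' `position` on `strand`, reading the trinucleotide 5'->3' on that strand.
#' `NA` when the base at `position` is not a cytosine on the given strand, or
#' when fewer than two downstream bases exist on that strand. Ambiguous bases
#' (`N`) count as "not G", so e.g. `CNG` classifies as CHG and `CNN` as CHH.
#'
#' @param sequence a single chromosome sequence (character or
#'   `Biostrings::DNAString`).
#' @param position 1-based position(s); recycled against `strand`.
#' @param strand `"+"` or `"-"`, the strand carrying the cytosine.
#' @return character vector of contexts, `NA` where undefined.
#' @examples
#' classify_context("ACGT", 2, "+")  # CG
#' classify_context("ACGT", 3, "-")  # CG (the C paired to the G)
#' classify_context("ACAG", 2, "+")  # CHG
#' @export
classify_context <- function(sequence, position, strand) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  n <- max(length(position), length(strand))
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(as.character(strand), n)
  if (any(position < 1L | position > L)) .stopf("position out of range")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- rep(NA_character_, n)
  plus <- strand == "+"
  ok <- plus & ch[position] == "C" & position <= L - 2L
  if (any(ok)) {
    out[ok] <- .context_from_tri(ch[position[ok] + 1L], ch[position[ok] + 2L])
  }
  ok <- !plus & ch[position] == "G" & position >= 3L
  if (any(ok)) {
    out[ok] <- .context_from_tri(unname(.complement[ch[position[ok] - 1L]]),
                                 unname(.complement[ch[position[ok] - 2L]]))
  }
  out
}

#' Enumerate every cytosine of a genome with its context
#'
#' Scans both strands of each chromosome and returns one row per cytosine
#' whose context is determined (at least two downstream bases on its strand).
#'
#' @param genome a named `Biostrings::DNAStringSet` or named character vector
#'   of chromosome sequences.
#' @param contexts optional subset of contexts to keep (filtering early is
#'   much cheaper than subsetting the full table afterwards).
#' @return a `data.frame` with columns `chrom, pos, strand, context, tri`
#'   (positions 1-based, trinucleotide 5'->3' on `strand`).
#' @export
cytosine_contexts <- function(genome, contexts = NULL) {
  seqs <- as.character(genome)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  per_chrom <- lapply(names(seqs), function(cn) {
    ch <- strsplit(toupper(seqs[[cn]]), "", fixed = TRUE)[[1L]]
    L <- length(ch)
    if (L < 3L) {
      return(data.frame(chrom = character(), pos = integer(), strand = character(),
                        context = character(), tri = character(), stringsAsFactors = FALSE))
    }
    ip <- which(ch == "C")
    ip <- ip[ip <= L - 2L]
    im <- which(ch == "G")
    im <- im[im >= 3L]
    b2p <- ch[ip + 1L]; b3p <- ch[ip + 2L]
    b2m <- unname(.complement[ch[im - 1L]]); b3m <- unname(.complement[ch[im - 2L]])
    df <- data.frame(
      chrom = cn,
      pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(.context_from_tri(b2p, b3p), .context_from_tri(b2m, b3m)),
      tri = c(paste0("C", b2p, b3p), paste0("C", b2m, b3m)),
      stringsAsFactors = FALSE
    )
    if (!is.null(contexts)) df <- df[df$context %in% contexts, , drop = FALSE]
    df[order(df$pos, df$strand), , drop = FALSE]
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out
}

#' Call methylcytosines (modified sites)
#'
#' Flags a covered cytosine as a methylcytosine when it has at least
#' `min_cov` covering reads and at least `min_meth_reads` reads supporting
#' methylation, and derives the per-site methylation level mC/(mC + non-mC).
#' The default coverage floor of 4 reads follows the read-support rule the
#' DMR criteria impose on methylated cytosines; both thresholds are
#' configurable.
#'
#' @param sites a cytosine report `data.frame`.
#' @param min_cov minimum total reads (default 4).
#' @param min_meth_reads minimum methylated reads (default 1).
#' @return `sites` with added columns `level` (in `[0,1]`) and `modified`
#'   (logical).
#' @export
call_modified_sites <- function(sites, min_cov = 4L, min_meth_reads = 1L) {
  stopifnot(min_cov >= 1L, min_meth_reads >= 1L)
  sites$level <- sites$meth / sites$total
  sites$modified <- sites$total >= min_cov & sites$meth >= min_meth_reads
  sites
}

#' Context shares of modified sites
#'
#' Each context's percentage of all methylcytosines: `100 * n(context) /
#' sum(n)`. This is the arithmetic behind per-context "proportion"
#' columns in genome-wide methylome summary tables.
#'
#' @param n_modified named counts of modified sites, names among
#'   `CG, CHG, CHH`.
#' @return named numeric percentages summing to 100.
#' @examples
#' context_shares(c(CG = 29369883, CHG = 23637970, CHH = 13739344))
#' @export
context_shares <- function(n_modified) {
  tot <- sum(n_modified)
  if (tot <= 0) .stopf("no modified sites: shares undefined")
  100 * n_modified / tot
}

#' Per-context methylome summary
#'
#' Counts methylcytosines per context, each context's share of all
#' methylcytosines, and the mean methylation level (unweighted mean of
#' per-site mC/(mC+non-mC) ratios over all covered sites of the context,
#' reported as a percent). Sites lacking a `modified` flag are first run
#' through [call_modified_sites()] with default thresholds.
#'
#' @param sites a cytosine report, ideally after [call_modified_sites()].
#' @param pooled if `TRUE`, `mean_level_pct` instead pools reads
#'   (`sum(meth)/sum(total)`), a sensitivity variant in which deeply covered
#'   sites weigh more.
#' @return a `data.frame` with one row per context: `context, n_modified,
#'   share_pct, mean_level_pct`.
#' @export
context_summary <- function(sites, pooled = FALSE) {
  if (is.null(sites$modified)) sites <- call_modified_sites(sites)
  n_mod <- vapply(.contexts, function(cx) sum(sites$modified & sites$context == cx), 0)
  shares <- context_shares(n_mod)
  lev <- vapply(.contexts, function(cx) {
    sel <- sites$context == cx
    if (!any(sel)) return(NA_real_)
    if (pooled) 100 * sum(sites$meth[sel]) / sum(sites$total[sel])
    else 100 * mean(sites$level[sel])
  }, 0)
  data.frame(context = .contexts, n_modified = unname(n_mod),
             share_pct = unname(shares), mean_level_pct = unname(lev),
             stringsAsFactors = FALSE)
}

#' Effective coverage rate
#'
#' Fraction of cytosine positions covered by at least one read. Arguments may
#' be counts or position vectors (the covered set must be a subset of the
#' full set).
#'
#' @param covered covered cytosines (count, or vector of positions).
#' @param all_cytosines all cytosines in the region (count or vector).
#' @return a fraction in `[0, 1]`.
#' @export
effective_coverage_rate <- function(covered, all_cytosines) {
  n_cov <- if (length(covered) == 1L && is.numeric(covered)) covered else length(covered)
  n_all <- if (length(all_cytosines) == 1L && is.numeric(all_cytosines)) all_cytosines else length(all_cytosines)
  if (n_all == 0) .stopf("empty cytosine set")
  if (n_cov > n_all) .stopf("covered set larger than full set")
  n_cov / n_all
}

#' Methylation-level histogram
#'
#' Site fractions in `n_bins` equal-width level bins from 0 to 100%. Bins are
#' left-closed; the last bin is right-closed so fully methylated sites land
#' in the top bin.
#'
#' @param sites a cytosine report (levels computed if absent).
#' @param context one of `CG, CHG, CHH`.
#' @param n_bins number of bins (default 10).
#' @return numeric vector of length `n_bins` summing to 1, named by bin
#'   interval.
#' @export
level_histogram <- function(sites, context, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  if (is.null(sites$level)) sites$level <- sites$meth / sites$total
  lev <- sites$level[sites$context == context]
  if (length(lev) == 0L) .stopf("no sites of context %s", context)
  bin <- pmin(floor(lev * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  lo <- round(100 * (seq_len(n_bins) - 1L) / n_bins)
  hi <- round(100 * seq_len(n_bins) / n_bins)
  setNames(counts / sum(counts), sprintf("[%d,%d%s", lo, hi, c(rep(")", n_bins - 1L), "]")))
}

#' Windowed mean-methylation track
#'
#' Tiles each chromosome with fixed windows from coordinate 0 and reports the
#' unweighted mean site level per window (per strand and context). Windows
#' with no sites are absent from the output rather than reported as zero;
#' with known chromosome lengths the final partial window is flagged.
#'
#' @param sites a cytosine report (levels computed if absent).
#' @param window_bp window width in bp (default 80000, a chromosome-scale
#'   track resolution).
#' @param strand_separated keep strands apart (default `TRUE`) or pool them.
#' @param context optional single context to restrict to.
#' @param chrom_lengths optional named chromosome lengths used to flag the
#'   final partial window.
#' @return a `data.frame` with columns `chrom, window_start, strand, context,
#'   mean_level, n_sites` (and `partial` when lengths are given),
#'   `window_start` 0-based.
#' @export
windowed_track <- function(sites, window_bp = 80000L, strand_separated = TRUE,
                           context = NULL, chrom_lengths = NULL) {
  stopifnot(window_bp > 0)
  if (is.null(sites$level)) sites$level <- sites$meth / sites$total
  if (!is.null(context)) sites <- sites[sites$context %in% context, , drop = FALSE]
  win <- as.integer(floor((sites$pos - 1L) / window_bp)) * as.integer(window_bp)
  strand_key <- if (strand_separated) sites$strand else "*"
  key <- interaction(sites$chrom, win, strand_key, sites$context, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(
    chrom = sites$chrom[first], window_start = win[first],
    strand = strand_key[first], context = sites$context[first],
    stringsAsFactors = FALSE
  )
  means <- tapply(sites$level, key, mean)
  ns <- tapply(seq_along(key), key, length)
  out$mean_level <- as.vector(means[as.character(key[first])])
  out$n_sites <- as.vector(ns[as.character(key[first])])
  if (!is.null(chrom_lengths)) {
    out$partial <- out$window_start + window_bp > chrom_lengths[out$chrom]
  }
  out <- out[order(out$chrom, out$window_start, out$strand, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}
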
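#' Construct a per-cytosine methylation report table
#'
#' The central per-site container: one row per covered cytosine, mirroring the
#' 7-column tab-separated reports emitted by bisulfite methylation callers.
#' Positions are 1-based; `strand` is the strand carrying the cytosine, and
#' `tri` is the trinucleotide read 5'->3' on that strand (so it always starts
#' with `C`).
#'
#' @param chrom chromosome identifiers.
#' @param pos 1-based cytosine positions.
#' @param strand `"+"` or `"-"`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param meth reads supporting methylation (mC).
#' @param total total covering reads (mC + non-mC), must be positive.
#' @param tri strand-oriented trinucleotide over `A,C,G,T,N`.
#' @return a `data.frame` with those seven columns.
#' @examples
#' cytosine_report("chr1", 10, "+", "CG", 3, 4, "CGT")
#' @export
cytosine_report <- function(chrom, pos, strand, context, meth, total, tri) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), context = as.character(context),
    meth = as.integer(meth), total = as.integer(total),
    tri = as.character(tri), stringsAsFactors = FALSE
  )
  bad <- .invalid_report_rows(df)
  if (any(bad)) .stopf("%d invalid cytosine report row(s)", sum(bad))
  df
}

# returns logical vector marking rows violating any report invariant
.invalid_report_rows <- function(df) {
  b2 <- substr(df$tri, 2L, 2L)
  b3 <- substr(df$tri, 3L, 3L)
  bad <- !(df$strand %in% c("+", "-")) |
    !(df$context %in% .contexts) |
    is.na(df$pos) | df$pos < 1L |
    is.na(df$meth) | is.na(df$total) |
    df$meth < 0L | df$total < 1L | df$meth > df$total |
    nchar(df$tri) != 3L | substr(df$tri, 1L, 1L) != "C" |
    !grepl("^[ACGTN]{3}$", df$tri) |
    df$context != .context_from_tri(b2, b3)
  bad
}

#' Read a 7-column per-cytosine methylation report
#'
#' Columns: chrom, pos (1-based), strand, context, methylated reads, total
#' reads, trinucleotide. A header line is tolerated and detected by a
#' non-numeric position field.
#'
#' @param path file path.
#' @param strict if `TRUE` (default) any invariant violation aborts; if
#'   `FALSE` violating rows are dropped with a message and counted in the
#'   `"n_dropped"` attribute of the result.
#' @return a cytosine report `data.frame` (see [cytosine_report()]), rows in
#'   file order.
#' @export
read_cytosine_report <- function(path, strict = TRUE) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    out <- cytosine_report(character(), integer(), character(), character(),
                           integer(), integer(), character())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  has_header <- is.na(suppressWarnings(as.integer(strsplit(first, "\t")[[1L]][2L])))
  df <- read.delim(path, header = has_header, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) != 7L) .stopf("expected 7 columns, found %d", ncol(df))
  names(df) <- c("chrom", "pos", "strand", "context", "meth", "total", "tri")
  df$pos <- as.integer(df$pos)
  df$meth <- as.integer(df$meth)
  df$total <- as.integer(df$total)
  bad <- .invalid_report_rows(df)
  if (any(bad)) {
    if (strict) .stopf("%d invalid row(s) in %s (strict mode)", sum(bad), path)
    .msgf("dropped %d invalid row(s) from %s", sum(bad), path)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_dropped") <- sum(bad)
  df
}

#' Write a per-cytosine methylation report
#'
#' Serializes to the 7-column TSV dialect read by [read_cytosine_report()];
#' the reader applied to the written file reproduces the input exactly.
#'
#' @param rows a cytosine report `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(rows, path) {
  write.table(rows[, c("chrom", "pos", "strand", "context", "meth", "total", "tri")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a feature annotation table
#'
#' Intervals are 0-based half-open. `exons` is a list column (one element per
#' feature) of two-column matrices of 0-based half-open sub-intervals, `NULL`
#' where a feature has no exon structure. TE class is derived from the family
#' when omitted (class I retrotransposons: Copia, Gypsy, LTR-Other, LINE,
#' SINE; class II DNA transposons: DNA-Other, hAT, MULE-MuDR, EnSpm,
#' Stowaway).
#'
#' @param id feature identifiers (unique).
#' @param chrom chromosome identifiers.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param kind `"gene"`, `"TE"` or `"lncRNA"`.
#' @param te_family TE family label, `NA` for non-TEs.
#' @param exons list of exon matrices or `NULL`.
#' @return a `data.frame` sorted by (chrom, start) with columns
#'   `id, chrom, start, end, strand, kind, te_class, te_family, exons`.
#' @export
feature_table <- function(id, chrom, start, end, strand, kind,
                          te_family = NA_character_, exons = NULL) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), kind = as.character(kind),
    te_class = .te_family_class(rep_len(as.character(te_family), n)),
    te_family = rep_len(as.character(te_family), n),
    stringsAsFactors = FALSE
  )
  if (is.null(exons)) exons <- vector("list", n)
  df$exons <- exons
  .validate_features(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.validate_features <- function(df) {
  if (anyDuplicated(df$id)) .stopf("duplicate feature ids")
  if (any(df$start >= df$end)) .stopf("feature with start >= end")
  if (!all(df$strand %in% c("+", "-"))) .stopf("feature strand must be + or -")
  if (!all(df$kind %in% c("gene", "TE", "lncRNA"))) .stopf("unknown feature kind")
  is_te <- df$kind == "TE"
  if (any(is_te & is.na(df$te_family)))
    .stopf("TE features need a family label")
  if (any(is_te & is.na(df$te_class)))
    .stopf("unknown TE family: %s",
           paste(unique(df$te_family[is_te & is.na(df$te_class)]), collapse = ", "))
  if (any(!is_te & !is.na(df$te_family)))
    .stopf("te_family set on a non-TE feature")
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex)) next
    if (any(ex[, 1L] < df$start[i]) || any(ex[, 2L] > df$end[i]))
      .stopf("exon outside feature %s", df$id[i])
    if (any(ex[, 1L] >= ex[, 2L])) .stopf("empty exon in feature %s", df$id[i])
    o <- order(ex[, 1L])
    if (nrow(ex) > 1L && any(ex[o, 1L][-1L] < ex[o, 2L][-nrow(ex)]))
      .stopf("overlapping exons in feature %s", df$id[i])
  }
  invisible(df)
}

#' Read gene/TE/lncRNA annotation from GFF3 or BED
#'
#' GFF3 records of type `gene`, `transposable_element` (or `TE`) and
#' `lnc_RNA`/`lncRNA` are kept; `exon` children are attached to their
#' `Parent`. TE families are read from a `family` attribute. BED6 records
#' become exon-less features of `feature_kind`; BED12 blocks become exons.
#' GFF3 1-based starts are decremented to the internal 0-based half-open
#' convention.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_kind kind assigned to BED records (BED carries none).
#' @return a feature table (see [feature_table()]).
#' @export
read_features <- function(path, format = c("gff3", "bed"), feature_kind = "gene") {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    type <- as.character(gr$type)
    kind_map <- c(gene = "gene", transposable_element = "TE", TE = "TE",
                  lnc_RNA = "lncRNA", lncRNA = "lncRNA")
    keep <- type %in% names(kind_map)
    top <- gr[keep]
    ids <- top$ID
    fam <- if (!is.null(top$family)) as.character(top$family) else rep(NA_character_, length(top))
    exons_gr <- gr[type == "exon"]
    exon_parent <- vapply(exons_gr$Parent, function(p) p[1L], character(1))
    exons <- lapply(ids, function(i) {
      e <- exons_gr[exon_parent == i]
      if (length(e) == 0L) return(NULL)
      m <- cbind(start = GenomicRanges::start(e) - 1L, end = GenomicRanges::end(e))
      m[order(m[, 1L]), , drop = FALSE]
    })
    feature_table(
      id = ids, chrom = as.character(GenomicRanges::seqnames(top)),
      start = GenomicRanges::start(top) - 1L, end = GenomicRanges::end(top),
      strand = as.character(GenomicRanges::strand(top)),
      kind = unname(kind_map[type[keep]]), te_family = fam, exons = exons
    )
  } else {
    exons <- vector("list", length(gr))
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      for (i in seq_along(gr)) {
        b <- bl[[i]]
        if (length(b) > 0L) {
          abs0 <- GenomicRanges::start(gr)[i] - 1L
          exons[[i]] <- cbind(start = abs0 + IRanges::start(b) - 1L,
                              end = abs0 + IRanges::end(b))
        }
      }
    }
    feature_table(
      id = if (!is.null(gr$name)) as.character(gr$name) else paste0("feat", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      kind = feature_kind, exons = exons
    )
  }
}

#' Write a feature table as GFF3
#'
#' Inverse of [read_features()] for the GFF3 dialect: internal 0-based starts
#' are re-incremented to the 1-based GFF3 convention; exons are emitted as
#' `exon` children; TE families as a `family` attribute.
#'
#' @param features a feature table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  type_map <- c(gene = "gene", TE = "transposable_element", lncRNA = "lnc_RNA")
  rows <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    attrs <- sprintf("ID=%s", f$id)
    if (f$kind == "TE") attrs <- paste0(attrs, ";family=", f$te_family)
    rows[[length(rows) + 1L]] <- sprintf("%s\tmethkit\t%s\t%d\t%d\t.\t%s\t.\t%s",
      f$chrom, type_map[[f$kind]], f$start + 1L, f$end, f$strand, attrs)
    ex <- features$exons[[i]]
    if (!is.null(ex)) {
      for (j in seq_len(nrow(ex))) {
        rows[[length(rows) + 1L]] <- sprintf(
          "%s\tmethkit\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          f$chrom, ex[j, 1L] + 1L, ex[j, 2L], f$strand, f$id, j, f$id)
      }
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read a per-feature expression table
#'
#' A TSV with header columns `id`, `count`, `rpkm`. One row per feature;
#' duplicate ids or negative values are errors.
#'
#' @param path file path.
#' @return a `data.frame` with columns `id`, `count`, `rpkm`.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "count", "rpkm") %in% names(df)))
    .stopf("expression table needs columns id, count, rpkm")
  df <- df[, c("id", "count", "rpkm")]
  if (anyDuplicated(df$id)) .stopf("duplicate feature id in expression table")
  if (any(df$count < 0) || any(df$rpkm < 0)) .stopf("negative expression value")
  df
}

#' @rdname read_expression_table
#' @param expr expression `data.frame` to serialize.
#' @export
write_expression_table <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called DMRs as BED6+
#'
#' Standard BED6 columns (name = context, score = -log10 p capped at 999,
#' strand = ".") followed by `level_A, level_B, fold_change, chi2, p,
#' direction`.
#'
#' @param dmrs a DMR table from [call_dmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(999, round(-log10(pmax(dmrs$p, .Machine$double.xmin)), 3))
  out <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = dmrs$context, score = score, strand = ".",
    level_A = signif(dmrs$level_A, 6), level_B = signif(dmrs$level_B, 6),
    fold_change = signif(dmrs$fold_change, 6), chi2 = signif(dmrs$chi2, 6),
    p = signif(dmrs$p, 6), direction = dmrs$direction,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write interval loci as BED6
#'
#' Used for 24-nt siRNA loci. Coordinates stay 0-based half-open end to end.
#'
#' @param path file path.
#' @return `read_bed_loci`: a `data.frame` with columns
#'   `chrom, start, end, name, score, strand`.
#' @export
read_bed_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_bed_loci
#' @param loci interval `data.frame` with at least `chrom, start, end`.
#' @export
write_bed_loci <- function(loci, path) {
  out <- data.frame(
    chrom = loci$chrom, start = loci$start, end = loci$end,
    name = loci$name %||% ".", score = loci$score %||% 0,
    strand = if (is.null(loci$strand)) "." else loci$strand,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
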
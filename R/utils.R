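`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.msgf <- function(...) message(sprintf(...))

#' @noRd
.contexts <- c("CG", "CHG", "CHH")

# class I = retrotransposons, class II = DNA transposons
.te_families <- list(
  I  = c("Copia", "Gypsy", "LTR-Other", "LINE", "SINE"),
  II = c("DNA-Other", "hAT", "MULE-MuDR", "EnSpm", "Stowaway")
)

.te_family_class <- function(family) {
  out <- rep(NA_character_, length(family))
  out[family %in% .te_families$I] <- "I"
  out[family %in% .te_families$II] <- "II"
  out
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# context from the 2nd and 3rd base of the strand-oriented trinucleotide;
# N (or any non-ACGT) counts as "not G"
.context_from_tri <- function(b2, b3) {
  ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
}

.is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(x == round(x))

# features data.frame -> GRanges (1-based closed, as GenomicRanges expects)
.features_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges   = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand   = features$strand,
    id       = features$id
  )
}
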
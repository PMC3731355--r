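#' GenotypeExperiment: biallelic SNP dosages with variant metadata
#'
#' An S4 container for unphased diploid genotypes over one resequenced
#' region, extending [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are biallelic variants (a `GRanges` with `id`, `ref`, `alt` and an
#' optional free-text `region_label` such as `"Intron 2"`), columns are
#' samples, and the single `"dosage"` assay holds alternate-allele counts in
#' `{0, 1, 2, NA}`.
#'
#' Variants are kept sorted by (chromosome, position); duplicated
#' (chrom, pos, ref, alt) records and multiallelic records are rejected, and
#' every variant must be called in at least one sample.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [readVCF()], [readGenotypeTSV()], [computeMAF()]
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    ok <- is.na(d) | d == 0L | d == 1L | d == 2L
    if (!all(ok)) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (nrow(d) > 0L) {
      called <- rowSums(!is.na(d))
      if (any(called == 0L))
        msg <- c(msg, "every variant needs >= 1 non-missing genotype")
    }
  }
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  need <- c("id", "ref", "alt")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, "rowRanges must carry mcols 'id', 'ref', 'alt'")
  else if (length(rr) > 0L) {
    if (any(grepl(",", mc$alt, fixed = TRUE)))
      msg <- c(msg, "multiallelic records are not supported (one ALT only)")
    if (any(mc$ref == mc$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    key <- paste(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr), mc$ref, mc$alt)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (chrom, pos, ref, alt) records")
    o <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    if (!identical(o, seq_along(rr)))
      msg <- c(msg, "variants must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosages integer matrix of alternate-allele counts, variants x
#'   samples, values in `{0, 1, 2, NA}`.
#' @param variants `data.frame` (or `GRanges`) with columns/mcols `chrom`,
#'   `pos` (1-based), `id`, `ref`, `alt` and optionally `region_label`; one
#'   row per dosage row. Input order may be arbitrary; variants are sorted
#'   by (chrom, pos).
#' @param samples character vector of sample identifiers (columns).
#' @return a [GenotypeExperiment-class] object.
#' @examples
#' ge <- GenotypeExperiment(
#'   dosages = matrix(c(0L, 1L, 2L, 1L, NA, 0L), nrow = 2, byrow = TRUE),
#'   variants = data.frame(chrom = "chr6", pos = c(100, 200),
#'                         id = c("snp1", "snp2"), ref = "A", alt = "G"),
#'   samples = c("s1", "s2", "s3"))
#' nVariants(ge)
#' @export
GenotypeExperiment <- function(dosages, variants, samples = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(dosages)))
  if (is(variants, "GRanges")) {
    rr <- variants
  } else {
    variants <- as.data.frame(variants)
    if (is.null(variants$region_label))
      variants$region_label <- rep(NA_character_, nrow(variants))
    rr <- GenomicRanges::GRanges(
      seqnames = as.character(variants$chrom),
      ranges = IRanges::IRanges(start = as.integer(variants$pos), width = 1L),
      id = as.character(variants$id),
      ref = as.character(variants$ref),
      alt = as.character(variants$alt),
      region_label = as.character(variants$region_label))
  }
  if (length(rr) != nrow(dosages))
    stop("variants and dosage rows disagree in length")
  if (any(GenomicRanges::start(rr) < 1L))
    stop("positions must be >= 1 (1-based coordinates)")
  o <- order(as.character(GenomicRanges::seqnames(rr)),
             GenomicRanges::start(rr))
  rr <- rr[o]
  dosages <- dosages[o, , drop = FALSE]
  dimnames(dosages) <- list(S4Vectors::mcols(rr)$id, samples)
  names(rr) <- S4Vectors::mcols(rr)$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages), rowRanges = rr)
  new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment number of variants (rows)
#' @param ge a `GenotypeExperiment`
#' @export
nVariants <- function(ge) nrow(ge)

#' @describeIn GenotypeExperiment number of samples (columns)
#' @export
nSamples <- function(ge) ncol(ge)

#' @describeIn GenotypeExperiment variant identifiers, in matrix order
#' @export
variantIds <- function(ge) S4Vectors::mcols(SummarizedExperiment::rowRanges(ge))$id

#' @describeIn GenotypeExperiment variant metadata as a data.frame
#'   (chrom, pos, id, ref, alt, region_label), in matrix order
#' @export
variantInfo <- function(ge) {
  rr <- SummarizedExperiment::rowRanges(ge)
  mc <- S4Vectors::mcols(rr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             id = mc$id, ref = mc$ref, alt = mc$alt,
             region_label = if ("region_label" %in% colnames(mc))
               mc$region_label else NA_character_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn GenotypeExperiment the dosage matrix (variants x samples)
#' @export
dosages <- function(ge) SummarizedExperiment::assay(ge, "dosage")

#' @export
setMethod("show", "GenotypeExperiment", function(object) {
  d <- dosages(object)
  cat("GenotypeExperiment:", nrow(object), "variants x", ncol(object),
      "samples\n")
  if (nrow(object) > 0L) {
    rr <- SummarizedExperiment::rowRanges(object)
    cat("  region:", as.character(GenomicRanges::seqnames(rr))[1L], ":",
        min(GenomicRanges::start(rr)), "-", max(GenomicRanges::start(rr)),
        "\n", sep = "")
    cat("  missing genotypes:", sum(is.na(d)), "of", length(d), "\n")
  }
  invisible(object)
})
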
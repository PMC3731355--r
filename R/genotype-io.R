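#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x) with per-sample `GT` fields into a
#' [GenotypeExperiment-class]. Dosages are alternate-allele counts; missing
#' calls (`./.` or `.`) become `NA`. Phased separators (`|`) are accepted.
#' Records with more than one ALT allele are rejected: split multiallelics
#' upstream (e.g. `bcftools norm -m-`).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a [GenotypeExperiment-class].
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  altl <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altl)
  if (nrow(gt) == 0L) {
    return(GenotypeExperiment(
      dosages = matrix(integer(), 0L, ncol(gt)),
      variants = data.frame(chrom = character(), pos = integer(),
                            id = character(), ref = character(),
                            alt = character()),
      samples = colnames(gt)))
  }
  if (any(nalt != 1L))
    stop("multiallelic record(s) at ",
         paste(head(names(rr)[nalt != 1L], 3L), collapse = ", "),
         ": only biallelic sites are supported")
  dos <- .decodeGT(gt)
  ids <- names(rr)
  if (is.null(ids) || any(ids == "" | is.na(ids)))
    ids <- paste0("snp_", as.character(GenomicRanges::seqnames(rr)), "_",
                  GenomicRanges::start(rr))
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = ids,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_along(altl), function(i) as.character(altl[[i]][1L]), ""),
    stringsAsFactors = FALSE)
  GenotypeExperiment(dos, variants, samples = colnames(gt))
}

# GT strings -> alt-allele dosage {0,1,2,NA}; errors name the offending value
.decodeGT <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1L]]
    if (length(a) != 2L || any(!a %in% c("0", "1", ".")))
      stop("unsupported GT value '", s, "'")
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
  m <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Read genotypes from a plain dosage matrix TSV
#'
#' Expects a header row of variant identifiers, a first column of sample
#' identifiers, and cells in `{0, 1, 2, NA}` (samples x variants). Variant
#' positions are taken from an optional companion `variants` table;
#' otherwise synthetic consecutive positions on chromosome `"un"` are
#' assigned so that downstream index-space windowing still works.
#'
#' @param path path to the TSV.
#' @param variants optional `data.frame(chrom, pos, id, ref, alt)` keyed by
#'   the header identifiers.
#' @return a [GenotypeExperiment-class].
#' @export
readGenotypeTSV <- function(path, variants = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(tab[[1L]])
  d <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(d) <- "integer"
  ids <- colnames(d)
  if (is.null(variants))
    variants <- data.frame(chrom = "un", pos = seq_along(ids), id = ids,
                           ref = "N", alt = "V", stringsAsFactors = FALSE)
  else
    variants <- variants[match(ids, variants$id), , drop = FALSE]
  GenotypeExperiment(t(d), variants, samples = samples)
}

#' Minor allele frequencies, orientation and call counts
#'
#' For each variant the alternate-allele frequency is
#' `f = sum(dosage) / (2 * n_called)` over non-missing samples; the minor
#' allele frequency is `min(f, 1 - f)`. `minor_is_alt` records which allele
#' is minor (`TRUE` when `f <= 0.5`; the tie at `f = 0.5` deterministically
#' treats ALT as minor so downstream statistic orientation is fixed).
#'
#' @param ge a [GenotypeExperiment-class] with at least one variant.
#' @return a [S4Vectors::DataFrame] with columns `maf`, `minor_is_alt`,
#'   `n_called`, row names the variant ids.
#' @export
computeMAF <- function(ge) {
  if (nVariants(ge) == 0L) stop("no variants")
  d <- dosages(ge)
  n_called <- rowSums(!is.na(d))
  if (any(n_called == 0L)) stop("variant with all genotypes missing")
  f <- unname(rowSums(d, na.rm = TRUE) / (2 * n_called))
  S4Vectors::DataFrame(maf = pmin(f, 1 - f), minor_is_alt = f <= 0.5,
                       n_called = as.integer(unname(n_called)),
                       row.names = variantIds(ge))
}

#' Filter variants by minor allele frequency
#'
#' Retains exactly the variants with `MAF > threshold` (strict inequality);
#' samples and relative variant order are unchanged.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param threshold frequency in `[0, 0.5)`; default 0.01.
#' @return the filtered [GenotypeExperiment-class].
#' @export
filterByMAF <- function(ge, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold < 0.5)
  maf <- computeMAF(ge)
  ge[maf$maf > threshold, ]
}

#' Pairwise LD as squared dosage correlation
#'
#' Genotypic (composite) linkage disequilibrium: the squared Pearson
#' correlation of the two unphased dosage columns over samples non-missing
#' at both variants. No phasing or haplotype model is involved, so the
#' value is invariant under allele re-orientation (`g -> 2 - g`) of either
#' variant.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param i,j variant indices or ids.
#' @return squared correlation in `[0, 1]`.
#' @export
ldR2 <- function(ge, i, j) {
  d <- dosages(ge)
  if (is.character(i)) i <- match(i, variantIds(ge))
  if (is.character(j)) j <- match(j, variantIds(ge))
  gi <- d[i, ]; gj <- d[j, ]
  keep <- !is.na(gi) & !is.na(gj)
  if (sum(keep) < 2L)
    stop("fewer than 2 samples jointly called for variants ", i, ", ", j)
  gi <- gi[keep]; gj <- gj[keep]
  if (sd(gi) == 0 || sd(gj) == 0)
    stop("LD undefined: constant dosage column on the complete subset",
         call. = FALSE)
  cor(gi, gj)^2
}

#' Write a MAF summary TSV
#'
#' Columns: `variant_id`, `chrom`, `pos`, `maf`, `minor_is_alt`, `n_called`.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param path output path.
#' @return the summary `data.frame`, invisibly.
#' @export
writeMafSummary <- function(ge, path) {
  maf <- computeMAF(ge)
  vi <- variantInfo(ge)
  out <- data.frame(variant_id = vi$id, chrom = vi$chrom, pos = vi$pos,
                    maf = maf$maf, minor_is_alt = maf$minor_is_alt,
                    n_called = maf$n_called)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

# Dosage matrix oriented to the minor allele (variants x samples); used by
# both scan statistics so orientation is decided once, from pooled MAF.
.minorDosages <- function(ge, maf = computeMAF(ge)) {
  d <- dosages(ge)
  flip <- !maf$minor_is_alt
  if (any(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d
}
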
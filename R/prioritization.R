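#' Select the top window of a scan
#'
#' The window minimizing the chosen p-value column, tie-broken by larger
#' statistic magnitude, then by smaller start index, so the selection is
#' deterministic.
#'
#' @param results a scan result ([dmafScan()] / [survivalScan()]).
#' @param pColumn which p-value to rank on (default `"p_unadjusted"`).
#' @return the selected result row (one-row `DataFrame`).
#' @export
topWindow <- function(results, pColumn = c("p_unadjusted", "p_adjusted")) {
  pColumn <- match.arg(pColumn)
  if (is.null(results) || nrow(results) == 0L) stop("empty scan results")
  o <- order(results[[pColumn]], -abs(results$statistic),
             results$start_index)
  results[o[1L], ]
}

#' Read transcription-factor annotation intervals from BED
#'
#' Thin wrapper over [rtracklayer::import()]: BED's 0-based half-open
#' intervals arrive as 1-based closed `GRanges`, so a SNP at 1-based
#' position `pos` overlaps the BED interval `[start, end)` exactly when
#' `pos - 1` lies in `[start, end)`. The BED name field carries the factor
#' label (e.g. `"GR"`, `"NFKB"`).
#'
#' @param path BED file path.
#' @return a `GRanges` with a `name` metadata column.
#' @export
readAnnotationBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name)) gr$name <- NA_character_
  gr
}

#' Annotate SNPs with overlapping transcription-factor intervals
#'
#' Returns the subset of the given variants falling inside at least one
#' annotation interval, each carrying every overlapping interval's label
#' (comma-joined, in interval order).
#'
#' @param ge a [GenotypeExperiment-class].
#' @param annotation a `GRanges` from [readAnnotationBed()] (or any
#'   `GRanges` with a `name` column).
#' @param ids optional variant ids restricting the query (e.g. a top
#'   window's SNPs); default all variants.
#' @return `data.frame(id, chrom, pos, labels)` for the overlapping SNPs.
#' @export
annotateTF <- function(ge, annotation, ids = variantIds(ge)) {
  sel <- match(ids, variantIds(ge))
  if (anyNA(sel)) stop("unknown variant id(s): ",
                       paste(head(ids[is.na(sel)], 3L), collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(ge)[sel]
  hits <- GenomicRanges::findOverlaps(rr, annotation, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      labels = character(), stringsAsFactors = FALSE))
  qh <- S4Vectors::queryHits(hits)
  labs <- vapply(split(S4Vectors::subjectHits(hits), qh), function(s)
    paste(unique(annotation$name[s]), collapse = ","), "")
  qi <- as.integer(names(labs))
  data.frame(id = S4Vectors::mcols(rr)$id[qi],
             chrom = as.character(GenomicRanges::seqnames(rr))[qi],
             pos = GenomicRanges::start(rr)[qi],
             labels = unname(labs), stringsAsFactors = FALSE)
}

#' Retain candidates in strong LD with a reference SNP set
#'
#' Keeps each candidate whose squared dosage correlation with at least one
#' reference variant exceeds `threshold` (strict). A candidate that is
#' itself in the reference set passes trivially (R^2 = 1 with itself).
#' Pairs with undefined LD (constant dosage on the jointly-called subset)
#' are treated as non-passing and counted in a message.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param candidates character vector of candidate variant ids.
#' @param reference character vector of reference variant ids.
#' @param threshold strict lower R^2 bound in `(0, 1]` (default 0.8).
#' @return the retained subset of `candidates`, in input order.
#' @export
ldCrossFilter <- function(ge, candidates, reference, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  undef <- 0L
  keep <- vapply(candidates, function(cid) {
    if (cid %in% reference) return(TRUE)
    for (rid in reference) {
      r2 <- tryCatch(ldR2(ge, cid, rid), error = function(e) {
        undef <<- undef + 1L
        NA_real_
      })
      if (!is.na(r2) && r2 > threshold) return(TRUE)
    }
    FALSE
  }, logical(1))
  if (undef > 0L)
    message(undef, " candidate/reference pair(s) with undefined LD ",
            "treated as non-passing")
  candidates[keep]
}

#' Build a candidate-SNP report
#'
#' One row per candidate: identifier, genomic location (position, plus the
#' free-text region label when present, as `"pos/label"`), MAF rendered as
#' a whole percent with `"<1%"` below 1%, and the transcription-factor
#' label(s).
#'
#' @param annotated `data.frame(id, chrom, pos, labels)` from
#'   [annotateTF()], already filtered to the final candidate set.
#' @param ge the [GenotypeExperiment-class] the candidates came from.
#' @return `data.frame(id, location, maf, tf)`.
#' @export
buildCandidateReport <- function(annotated, ge) {
  if (nrow(annotated) == 0L)
    return(data.frame(id = character(), location = character(),
                      maf = character(), tf = character(),
                      stringsAsFactors = FALSE))
  maf <- computeMAF(ge)
  vi <- variantInfo(ge)
  sel <- match(annotated$id, vi$id)
  loc <- ifelse(is.na(vi$region_label[sel]), as.character(vi$pos[sel]),
                paste0(vi$pos[sel], "/", vi$region_label[sel]))
  m <- maf$maf[sel]
  maf_str <- ifelse(m < 0.01, "<1%", sprintf("%.0f%%", 100 * m))
  data.frame(id = annotated$id, location = loc, maf = maf_str,
             tf = annotated$labels, stringsAsFactors = FALSE)
}

#' Run the candidate-SNP prioritization cascade
#'
#' The selection cascade applied after both scans: (1) take the SNPs of the
#' top survival window; (2) keep those inside transcription-factor binding
#' intervals; (3) keep those in strong LD (`R^2 > ldThreshold`) with at
#' least one SNP of the top expression window; (4) format the survivors as
#' a candidate report. All four stages are returned so that the set
#' inclusions `report` \eqn{\subseteq} `ld_filtered` \eqn{\subseteq}
#' `annotated` \eqn{\subseteq} `top window SNPs` can be checked on every
#' run.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param survResults scan result from [survivalScan()].
#' @param exprResults scan result from [dmafScan()].
#' @param annotation `GRanges` of TF intervals ([readAnnotationBed()]).
#' @param ldThreshold strict R^2 bound (default 0.8).
#' @param pColumn p-value column used to pick top windows.
#' @return a list with elements `survival_window`, `expression_window`
#'   (one-row result frames), `window_snps`, `annotated`, `ld_filtered`
#'   (id vectors / data.frame), and `report`.
#' @export
prioritizeCandidates <- function(ge, survResults, exprResults, annotation,
                                 ldThreshold = 0.8,
                                 pColumn = "p_unadjusted") {
  sw <- topWindow(survResults, pColumn)
  ew <- topWindow(exprResults, pColumn)
  winSnps <- windowVariants(ge, sw$start_index, sw$window_size)
  refSnps <- windowVariants(ge, ew$start_index, ew$window_size)
  ann <- annotateTF(ge, annotation, ids = winSnps)
  ldPass <- ldCrossFilter(ge, ann$id, refSnps, threshold = ldThreshold)
  annKept <- ann[ann$id %in% ldPass, , drop = FALSE]
  report <- buildCandidateReport(annKept, ge)
  stopifnot(all(report$id %in% ldPass), all(ldPass %in% ann$id),
            all(ann$id %in% winSnps))
  list(survival_window = sw, expression_window = ew, window_snps = winSnps,
       annotated = ann, ld_filtered = ldPass, report = report)
}
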
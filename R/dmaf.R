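#' Dichotomize an expression phenotype at its median
#'
#' Probe values are averaged per sample (arithmetic mean over the supplied
#' probe columns) and the mean is split at its median: samples strictly
#' above the median form group 1, all others -- including samples exactly at
#' the median -- form group 0. The at-median rule is deterministic so that
#' repeated runs reproduce the same grouping.
#'
#' @param probes numeric matrix or data.frame of probe values, samples x
#'   probes (a bare numeric vector is treated as a single probe).
#' @return a [S4Vectors::DataFrame] with columns `mean` and `group`
#'   (integer 0/1), row names the sample names when available.
#' @export
dichotomizeAtMedian <- function(probes) {
  if (is.null(dim(probes))) probes <- matrix(probes, ncol = 1L,
                                             dimnames = list(names(probes), NULL))
  probes <- as.matrix(probes)
  if (nrow(probes) < 2L) stop("need >= 2 samples")
  if (anyNA(probes)) stop("probe values must be complete")
  m <- rowMeans(probes)
  if (diff(range(m)) == 0)
    stop("degenerate phenotype: all probe means identical")
  grp <- as.integer(m > median(m))
  if (!any(grp == 1L) || !any(grp == 0L))
    stop("degenerate dichotomy: one group is empty")
  S4Vectors::DataFrame(mean = m, group = grp, row.names = rownames(probes))
}

#' DMAF statistic for one window
#'
#' The difference-in-minor-allele-frequency statistic for a marker set:
#' `D = sum over window markers of (f1 - f0)` where `f_g` is the
#' minor-allele frequency among non-missing samples of group `g`, with the
#' minor allele fixed from the pooled MAF orientation. Inference is
#' two-sided on `|D|`. A marker with all genotypes missing inside one group
#' is skipped (contributes 0) with a warning.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param groups integer 0/1 group labels per sample, or the result of
#'   [dichotomizeAtMedian()].
#' @param start,size the window (1-based start index, marker count).
#' @param statType `"signed"` (default) sums signed per-marker differences;
#'   `"absolute"` sums `|f1 - f0|`.
#' @return the statistic (signed for `"signed"`, nonnegative for
#'   `"absolute"`).
#' @export
dmafStatistic <- function(ge, groups, start, size,
                          statType = c("signed", "absolute")) {
  statType <- match.arg(statType)
  grp <- .asGroups(groups, nSamples(ge))
  d <- .minorDosages(ge)[seq(start, start + size - 1L), , drop = FALSE]
  .warnGroupMissing(d, grp)
  f1 <- .groupFreq(d, grp == 1L)
  f0 <- .groupFreq(d, grp == 0L)
  diff <- f1 - f0
  diff[is.na(diff)] <- 0
  if (statType == "absolute") sum(abs(diff)) else sum(diff)
}

.groupFreq <- function(d, sel) {
  sub <- d[, sel, drop = FALSE]
  called <- rowSums(!is.na(sub))
  ifelse(called > 0L, rowSums(sub, na.rm = TRUE) / (2 * called), NA_real_)
}

.warnGroupMissing <- function(d, grp) {
  miss <- rowSums(!is.na(d[, grp == 1L, drop = FALSE])) == 0L |
          rowSums(!is.na(d[, grp == 0L, drop = FALSE])) == 0L
  if (any(miss))
    warning(sum(miss), " marker(s) with no called genotypes in one group ",
            "skipped (contribute 0)")
  miss
}

.asGroups <- function(groups, n) {
  if (is(groups, "DataFrame") || is.data.frame(groups)) groups <- groups$group
  grp <- as.integer(groups)
  if (length(grp) != n) stop("group labels and samples disagree in length")
  if (!all(grp %in% c(0L, 1L))) stop("group labels must be 0/1")
  if (!any(grp == 1L) || !any(grp == 0L)) stop("both groups must be nonempty")
  grp
}

#' Sliding-window DMAF scan with permutation p-values
#'
#' Computes the DMAF statistic for every window of the plan and calibrates
#' it by permuting the group labels, holding genotypes fixed. Per window,
#' `p_unadjusted = (1 + #\{b : |D_b| >= |D_obs|\}) / (1 + B)`; per window
#' size, `p_adjusted` compares `|D_obs|` against the permutation
#' distribution of the maximum `|D|` over all windows of that size (the
#' same permutations are shared across windows, and the whole region forms
#' its own size class). When the number of distinct relabelings
#' `choose(n, n1)` is at most `exhaustiveCap`, exhaustive enumeration
#' replaces Monte Carlo and p-values are exact fractions.
#'
#' @inheritParams dmafStatistic
#' @param plan a [scanPlan()].
#' @param B number of random permutations (default 50000).
#' @param seed RNG seed for reproducibility.
#' @param exhaustiveCap switch to exhaustive enumeration when the distinct
#'   relabeling count is at or below this (default 10000).
#' @return a [S4Vectors::DataFrame], one row per window: `window_size`,
#'   `start_index`, `start_pos`, `end_pos`, `n_markers`, `whole_region`,
#'   `statistic`, `p_unadjusted`, `p_adjusted`, plus metadata columns
#'   `n_permutations` and `exhaustive`.
#' @export
dmafScan <- function(ge, groups, plan = scanPlan(), B = 50000, seed = NULL,
                     statType = c("signed", "absolute"),
                     exhaustiveCap = 10000) {
  statType <- match.arg(statType)
  if (B < 1) stop("B must be >= 1")
  n <- nSamples(ge)
  if (n < 4L) stop("need n >= 4 samples")
  grp <- .asGroups(groups, n)
  wins <- .planWindows(plan, nVariants(ge))
  d <- .minorDosages(ge)
  suppressWarnings(.warnGroupMissing(d, grp)) -> miss
  if (any(miss))
    warning(sum(miss), " marker(s) uncallable in one group contribute 0")

  n1 <- sum(grp == 1L)
  nLab <- choose(n, n1)
  exhaustive <- is.finite(nLab) && nLab <= exhaustiveCap
  if (exhaustive) {
    labMat <- .allLabelings(n, n1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    labMat <- t(vapply(seq_len(B), function(b) sample(grp), integer(n)))
  }
  res <- cpp_dmaf_scan(d, grp, labMat, wins$start, wins$size, wins$group,
                       statType == "absolute")
  nb <- nrow(labMat)
  if (exhaustive) {
    p_un <- res$count_unadjusted / nb
    p_adj <- res$count_adjusted / nb
  } else {
    p_un <- (1 + res$count_unadjusted) / (1 + nb)
    p_adj <- (1 + res$count_adjusted) / (1 + nb)
  }
  pos <- variantInfo(ge)$pos
  S4Vectors::DataFrame(
    window_size = wins$size, start_index = wins$start,
    start_pos = pos[wins$start], end_pos = pos[wins$start + wins$size - 1L],
    n_markers = wins$size, whole_region = wins$whole_region,
    statistic = res$statistic, p_unadjusted = p_un, p_adjusted = p_adj,
    n_permutations = nb, exhaustive = exhaustive)
}

# All distinct 0/1 labelings with n1 ones (rows). Used for exhaustive
# permutation inference at small n.
.allLabelings <- function(n, n1) {
  cmb <- combn(n, n1)
  out <- matrix(0L, ncol(cmb), n)
  for (k in seq_len(ncol(cmb))) out[k, cmb[, k]] <- 1L
  out
}

# All permutations of 1..n (rows); n! must stay modest (n <= 8 in practice).
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

#' Write a window-scan result TSV
#'
#' @param results a scan result from [dmafScan()] or [survivalScan()].
#' @param path output path.
#' @return the `data.frame` written, invisibly.
#' @export
writeScanResults <- function(results, path) {
  out <- as.data.frame(results)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
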
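#' Per-sample burden score over a window
#'
#' The count of minor alleles a sample carries across the window's
#' variants, with dosages oriented to the minor allele from the pooled MAF
#' (or taken as raw alternate-allele counts with
#' `orientation = "alt"`). A missing dosage contributes 0, keeping scores
#' integral and conservative toward the null.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param start,size the window (1-based start index, marker count).
#' @param orientation `"minor"` (default) or `"alt"`.
#' @return integer vector of scores, one per sample, in `[0, 2 * size]`.
#' @export
burdenScore <- function(ge, start, size, orientation = c("minor", "alt")) {
  orientation <- match.arg(orientation)
  d <- if (orientation == "minor") .minorDosages(ge) else dosages(ge)
  d <- d[seq(start, start + size - 1L), , drop = FALSE]
  d[is.na(d)] <- 0L
  as.integer(colSums(d))
}

#' CoxFit: a single-covariate Cox proportional-hazards fit
#'
#' Result of maximizing the Breslow-tie partial log-likelihood for one
#' scalar covariate by safeguarded Newton ascent. `divergent` flags
#' monotone-likelihood cases where `|beta|` hit the cap; the capped fit is
#' still reported so observed and permuted statistics are computed
#' identically.
#'
#' @slot beta log hazard ratio per covariate unit.
#' @slot loglik_at_beta maximized partial log-likelihood.
#' @slot loglik_at_zero null partial log-likelihood.
#' @slot lrt `2 * (loglik_at_beta - loglik_at_zero)`, >= 0.
#' @slot converged,divergent logical flags.
#' @export
setClass("CoxFit", representation(beta = "numeric",
                                  loglik_at_beta = "numeric",
                                  loglik_at_zero = "numeric",
                                  lrt = "numeric",
                                  converged = "logical",
                                  divergent = "logical"))

#' @export
setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit: beta = %.6g (HR = %.4g), LRT = %.6g%s\n",
              object@beta, exp(object@beta), object@lrt,
              if (object@divergent) " [divergent: monotone likelihood]"
              else ""))
  invisible(object)
})

#' Fit a single-covariate Cox model by partial-likelihood Newton ascent
#'
#' Maximizes the Breslow partial log-likelihood
#' `l(beta) = sum over event times [ sum_{events at t} beta * x_i -
#' d_t * log sum_{at risk at t} exp(beta * x_j) ]`
#' for one covariate. The likelihood is concave in `beta`, so Newton with
#' step-halving increases `l` monotonically; when the likelihood is
#' monotone (perfect separation of risk), `beta` is capped at
#' `+/- betaCap` and the fit flagged `divergent`.
#'
#' @param x numeric covariate, one value per sample.
#' @param time positive survival/censoring times.
#' @param event 1 = event observed, 0 = right-censored.
#' @param betaCap cap on `|beta|` (default 15; hazard ratios beyond
#'   `exp(15)` are numerically indistinguishable).
#' @return a [CoxFit-class].
#' @examples
#' fit <- coxFit(c(1, 0, 2, 0, 1, 2), time = c(5, 8, 2, 10, 7, 3),
#'               event = c(1, 1, 1, 0, 1, 0))
#' fit@lrt
#' @export
coxFit <- function(x, time, event, betaCap = 15) {
  n <- length(x)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 2L) stop("need >= 2 samples")
  if (anyNA(x) || anyNA(time) || anyNA(event)) stop("inputs must be complete")
  if (any(time <= 0)) stop("times must be > 0")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  if (sum(event) == 0L) stop("no events observed")
  o <- order(time)
  r <- cpp_cox_fit(as.numeric(x)[o], as.numeric(time)[o], event[o], betaCap)
  new("CoxFit", beta = r$beta, loglik_at_beta = r$loglik_at_beta,
      loglik_at_zero = r$loglik_at_zero, lrt = r$lrt,
      converged = r$converged, divergent = r$divergent)
}

#' Sliding-window burden-score Cox scan with permutation p-values
#'
#' For every window of the plan, the per-sample burden score enters a
#' single-covariate Cox model and the likelihood-ratio statistic
#' `LRT = 2 * (l(beta_hat) - l(0))` is calibrated by jointly permuting the
#' `(time, event)` pairs across samples -- breaking genotype linkage while
#' preserving the survival distribution. Per window,
#' `p_unadjusted = (1 + #\{b : LRT_b >= LRT_obs\}) / (1 + B)`; per window
#' size, `p_adjusted` uses the permutation distribution of the maximum LRT
#' over windows of that size. Divergent (monotone-likelihood) fits
#' contribute their capped LRT identically in observed and permuted scans.
#' With `factorial(n) <= exhaustiveCap` the full permutation group is
#' enumerated and p-values are exact.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param time,event survival phenotype (times > 0; event 1 = death
#'   observed, 0 = censored). Samples with a missing survival field are
#'   dropped with a message.
#' @param plan a [scanPlan()].
#' @param B number of random permutations (default 50000).
#' @param seed RNG seed.
#' @param betaCap cap on `|beta|` per fit (default 15).
#' @param orientation burden allele orientation, `"minor"` or `"alt"`.
#' @param exhaustiveCap exhaustive-enumeration switch (default 10000).
#' @return a [S4Vectors::DataFrame], one row per window: `window_size`,
#'   `start_index`, `start_pos`, `end_pos`, `n_markers`, `whole_region`,
#'   `statistic` (the LRT), `beta`, `divergent`, `p_unadjusted`,
#'   `p_adjusted`, `n_permutations`, `exhaustive`.
#' @export
survivalScan <- function(ge, time, event, plan = scanPlan(), B = 50000,
                         seed = NULL, betaCap = 15,
                         orientation = c("minor", "alt"),
                         exhaustiveCap = 10000) {
  orientation <- match.arg(orientation)
  if (B < 1) stop("B must be >= 1")
  n0 <- nSamples(ge)
  stopifnot(length(time) == n0, length(event) == n0)
  keep <- !is.na(time) & !is.na(event)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " sample(s) with missing survival data")
    ge <- ge[, keep]; time <- time[keep]; event <- event[keep]
  }
  n <- nSamples(ge)
  if (any(time <= 0)) stop("times must be > 0")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events observed")

  wins <- .planWindows(plan, nVariants(ge))
  d <- if (orientation == "minor") .minorDosages(ge) else dosages(ge)
  d[is.na(d)] <- 0L
  # prefix sums over markers -> burden of any contiguous window in O(1)
  cs <- rbind(0, apply(d, 2L, cumsum))            # (M+1) x n
  burden <- t(cs[wins$start + wins$size, , drop = FALSE] -
              cs[wins$start, , drop = FALSE])      # n x W

  sidx <- order(time)
  exhaustive <- n <= 12 && factorial(n) <= exhaustiveCap
  if (exhaustive) {
    perms <- .allPermutations(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  }
  permIdx <- perms[, sidx, drop = FALSE]  # covariate source per sorted slot
  res <- cpp_survival_scan(burden, sidx, time[sidx], event[sidx], permIdx,
                           wins$group, betaCap)
  nb <- nrow(perms)
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
    statistic = res$lrt, beta = res$beta, divergent = res$divergent,
    p_unadjusted = p_un, p_adjusted = p_adj,
    n_permutations = nb, exhaustive = exhaustive)
}
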
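# Independent oracles and small fixture builders shared across tests.
# Everything here is written against the definitions, not the package
# internals, so implementation and oracle stay separate routes.

# Build a GenotypeExperiment from a variants x samples dosage matrix.
toyGE <- function(d, pos = NULL, chrom = "chr6", ids = NULL,
                  region_label = NA_character_) {
  d <- as.matrix(d)
  M <- nrow(d)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = M)
  if (is.null(ids)) ids <- paste0("v", seq_len(M))
  GenotypeExperiment(
    d,
    data.frame(chrom = chrom, pos = pos, id = ids, ref = "A", alt = "G",
               region_label = region_label),
    samples = paste0("s", seq_len(ncol(d))))
}

# Breslow partial log-likelihood, written marker-by-marker from the
# definition (distinct event times, shared risk set for ties).
oracleBreslowLoglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# 1-D maximization of the same likelihood by golden-section/parabolic
# search; returns beta and the likelihood-ratio statistic.
oracleCoxFit <- function(x, time, event, lower = -15, upper = 15) {
  opt <- stats::optimize(function(b) oracleBreslowLoglik(b, x, time, event),
                         c(lower, upper), maximum = TRUE, tol = 1e-10)
  ll0 <- oracleBreslowLoglik(0, x, time, event)
  list(beta = opt$maximum, lrt = 2 * (opt$objective - ll0))
}

# DMAF by direct per-marker frequency tabulation over a minor-allele
# dosage matrix (variants x samples); markers uncallable in a group
# contribute 0.
oracleDmaf <- function(minorDos, grp, absolute = FALSE) {
  D <- 0
  for (m in seq_len(nrow(minorDos))) {
    g1 <- minorDos[m, grp == 1]; g1 <- g1[!is.na(g1)]
    g0 <- minorDos[m, grp == 0]; g0 <- g0[!is.na(g0)]
    if (length(g1) == 0 || length(g0) == 0) next
    diff <- sum(g1) / (2 * length(g1)) - sum(g0) / (2 * length(g0))
    D <- D + if (absolute) abs(diff) else diff
  }
  D
}

# All permutations of 1..n, iteratively (insertion construction).
oraclePermutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  if (n == 1L) return(out)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(slot) {
      cbind(out[, seq_len(slot - 1L), drop = FALSE], k,
            out[, seq(slot, k - 1L)[seq_len(k - slot)], drop = FALSE])
    }))
  }
  storage.mode(out) <- "integer"
  colnames(out) <- NULL
  out
}

# Write a VCF body from explicit GT strings (for reader tests).
writeToyVCF <- function(path, records, samples = c("s1", "s2", "s3")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
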
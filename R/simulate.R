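#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a small resequenced clinical cohort: 60 samples, 404
#' biallelic SNPs over one contiguous ~160 kb region, a MAF spectrum mixing
#' sub-1% rare variants (fraction `rare_fraction`, true frequency
#' Uniform(0.001, 0.01)) with common ones (Uniform(0.01, 0.5)), blockwise
#' linkage disequilibrium from haplotype-pool copying, right-censored
#' exponential survival and a quantitative expression phenotype optionally
#' driven by the burden of a planted causal window.
#'
#' @param n_samples cohort size (default 60).
#' @param n_variants SNPs in the region (default 404).
#' @param rare_fraction fraction of variants drawn from the rare spectrum
#'   (default 0.19, so roughly 81% of variants realize MAF > 1% at n = 60).
#' @param ld_block_size variants per correlated haplotype block (default
#'   20; 1 gives independent variants).
#' @param ld_rho latent AR(1) correlation between adjacent sites within a
#'   block (default 0.9; 0 gives independent sites, larger = stronger and
#'   longer-ranged within-block LD).
#' @param causal_window `NULL` or `c(start, size)` (1-based marker index).
#' @param expression_effect per-burden-unit shift of the latent expression
#'   mean (default 0).
#' @param survival_log_hr per-burden-unit log hazard ratio (default 0).
#' @param censoring_rate target fraction of censored samples (default 0.3).
#' @param noise_sd latent expression noise SD (default 1).
#' @param probe_noise_sd independent per-probe noise SD (default 0.5).
#' @param n_probes expression probes per sample (default 3).
#' @param baseline_expression latent mean on a log2 array-like scale
#'   (default 8).
#' @param baseline_hazard exponential event rate at burden 0, per month
#'   (default `log(2)/20`: 20-month median survival).
#' @param missing_rate fraction of genotype calls masked to `NA`
#'   (default 0).
#' @param seed integer RNG seed.
#' @return a validated `SimulationConfig` (a classed list).
#' @export
simulationConfig <- function(n_samples = 60, n_variants = 404,
                             rare_fraction = 0.19, ld_block_size = 20,
                             ld_rho = 0.9, causal_window = NULL,
                             expression_effect = 0, survival_log_hr = 0,
                             censoring_rate = 0.3, noise_sd = 1,
                             probe_noise_sd = 0.5, n_probes = 3,
                             baseline_expression = 8,
                             baseline_hazard = log(2) / 20,
                             missing_rate = 0, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              rare_fraction = rare_fraction,
              ld_block_size = as.integer(ld_block_size),
              ld_rho = ld_rho,
              causal_window = if (is.null(causal_window)) NULL
                              else as.integer(causal_window),
              expression_effect = expression_effect,
              survival_log_hr = survival_log_hr,
              censoring_rate = censoring_rate, noise_sd = noise_sd,
              probe_noise_sd = probe_noise_sd,
              n_probes = as.integer(n_probes),
              baseline_expression = baseline_expression,
              baseline_hazard = baseline_hazard,
              missing_rate = missing_rate, seed = as.integer(seed))
  .validateConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

.validateConfig <- function(cfg) {
  with(cfg, {
    stopifnot(n_samples >= 2, n_variants >= 1, ld_block_size >= 1,
              rare_fraction >= 0, rare_fraction <= 1,
              ld_rho >= 0, ld_rho < 1,
              censoring_rate >= 0, censoring_rate < 1,
              noise_sd >= 0, probe_noise_sd >= 0, n_probes >= 1,
              baseline_hazard > 0, missing_rate >= 0, missing_rate < 1)
    if (!is.null(causal_window)) {
      stopifnot(length(causal_window) == 2L, causal_window[1L] >= 1L,
                causal_window[1L] + causal_window[2L] - 1L <= n_variants)
    }
  })
  invisible(cfg)
}

#' Simulate a genotype matrix with blockwise LD
#'
#' Each sample draws two independent haplotypes from a population
#' haplotype distribution defined per block of `ld_block_size` variants: a
#' latent standard-normal AR(1) process with correlation `ld_rho` is
#' thresholded at `qnorm(f_m)`, so the allele at site `m` is carried
#' exactly with its target population frequency `f_m` while adjacent sites
#' are positively dependent (genuine within-block LD, including co-carried
#' rare alleles). Because haplotypes are sampled i.i.d. from that
#' population, realized per-variant allele counts are Binomial(2n, f_m) --
#' the sampling dispersion a real cohort of this size shows. Dosages are
#' the integer sum of the two haplotypes. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulationConfig()].
#' @return a [GenotypeExperiment-class].
#' @export
simulateGenotypes <- function(cfg) {
  .validateConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples; M <- cfg$n_variants
  rare <- runif(M) < cfg$rare_fraction
  f <- ifelse(rare, runif(M, 0.001, 0.01), runif(M, 0.01, 0.5))
  blocks <- split(seq_len(M), (seq_len(M) - 1L) %/% cfg$ld_block_size)
  H <- 2L * n
  d <- matrix(0L, M, n)
  for (idx in blocks) {
    L <- length(idx)
    Z <- matrix(rnorm(H * L), H, L)
    if (cfg$ld_rho > 0 && L > 1L) {
      s <- sqrt(1 - cfg$ld_rho^2)
      for (m in 2:L) Z[, m] <- cfg$ld_rho * Z[, m - 1L] + s * Z[, m]
    }
    hap <- t(Z) <= stats::qnorm(f[idx])          # L x H, marginals Bern(f)
    d[idx, ] <- hap[, seq(1L, H, 2L), drop = FALSE] +
                hap[, seq(2L, H, 2L), drop = FALSE]
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(M * n) < cfg$missing_rate, M, n)
    allmiss <- rowSums(!mask) == 0L
    if (any(allmiss)) mask[allmiss, 1L] <- FALSE  # keep >=1 call per variant
    d[mask] <- NA_integer_
  }
  pos <- sort(sample.int(160000L, M)) + 35541000L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  variants <- data.frame(chrom = "chr6", pos = pos,
                         id = sprintf("snp%04d", seq_len(M)),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  GenotypeExperiment(d, variants,
                     samples = sprintf("sample%02d", seq_len(n)))
}

# alt-allele burden of the causal window (0 everywhere when none is planted)
.causalBurden <- function(ge, cfg) {
  if (is.null(cfg$causal_window)) return(numeric(nSamples(ge)))
  s <- cfg$causal_window[1L]; w <- cfg$causal_window[2L]
  d <- dosages(ge)[seq(s, s + w - 1L), , drop = FALSE]
  d[is.na(d)] <- 0L
  colSums(d)
}

#' Simulate expression probe values
#'
#' Latent per-sample expression is
#' `baseline + expression_effect * burden(causal window) + N(0, noise_sd)`;
#' each of the `n_probes` probe columns adds independent
#' `N(0, probe_noise_sd)` probe noise, mimicking several array probe sets
#' measuring one transcript.
#'
#' @param ge a [GenotypeExperiment-class] from [simulateGenotypes()].
#' @param cfg the same [simulationConfig()].
#' @param seed RNG seed; defaults to `cfg$seed + 1`.
#' @return numeric matrix, samples x probes, named `probe_1 ...`.
#' @export
simulateExpression <- function(ge, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  n <- nSamples(ge)
  latent <- cfg$baseline_expression +
    cfg$expression_effect * .causalBurden(ge, cfg) +
    rnorm(n, 0, cfg$noise_sd)
  probes <- latent + matrix(rnorm(n * cfg$n_probes, 0, cfg$probe_noise_sd),
                            n, cfg$n_probes)
  dimnames(probes) <- list(colnames(ge),
                           paste0("probe_", seq_len(cfg$n_probes)))
  probes
}

#' Simulate right-censored survival
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(survival_log_hr * burden(causal window))`
#' (a proportional-hazards data-generating process); censoring times are
#' independent exponentials whose rate is calibrated so the expected
#' censored fraction matches `censoring_rate`. Observed time is the
#' minimum, `event` indicates the event came first.
#'
#' @inheritParams simulateExpression
#' @param seed RNG seed; defaults to `cfg$seed + 2`.
#' @return `data.frame(time, event)`, rows aligned to the samples.
#' @export
simulateSurvival <- function(ge, cfg, seed = cfg$seed + 2L) {
  set.seed(seed)
  n <- nSamples(ge)
  rate <- cfg$baseline_hazard * exp(cfg$survival_log_hr * .causalBurden(ge, cfg))
  tt <- rexp(n, rate)
  if (cfg$censoring_rate > 0) {
    crate <- mean(rate) * cfg$censoring_rate / (1 - cfg$censoring_rate)
    cc <- rexp(n, crate)
    data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc),
               row.names = colnames(ge))
  } else {
    data.frame(time = tt, event = 1L, row.names = colnames(ge))
  }
}

#' Simulate a complete cohort
#'
#' Genotypes, expression probes and survival in one call; phenotypes are
#' also attached to the `colData` of the returned genotypes.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `ge` (a [GenotypeExperiment-class] carrying phenotype
#'   `colData`), `probes` (matrix), and `survival` (`data.frame`).
#' @export
simulateCohort <- function(cfg) {
  ge <- simulateGenotypes(cfg)
  probes <- simulateExpression(ge, cfg)
  surv <- simulateSurvival(ge, cfg)
  cd <- S4Vectors::DataFrame(surv, probes)
  SummarizedExperiment::colData(ge) <- cd
  list(ge = ge, probes = probes, survival = surv)
}

#' Write a GenotypeExperiment as VCF
#'
#' Emits a minimal VCF v4.2 body (GT-only FORMAT) that round-trips through
#' [readVCF()] bit-identically. Dosage 0/1/2 becomes `0/0`, `0/1`, `1/1`;
#' `NA` becomes `./.`.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(ge, path) {
  vi <- variantInfo(ge)
  d <- dosages(ge)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(ge)), collapse = "\t"))
  body <- apply(cbind(vi$chrom, vi$pos, vi$id, vi$ref, vi$alt, ".", ".",
                      ".", "GT", gt), 1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype table TSV
#'
#' Expects columns `sample_id`, `time`, `event` and one or more probe
#' columns (any remaining numeric columns).
#'
#' @param path TSV path.
#' @return `data.frame` with `sample_id`, `time`, `event` and probe columns.
#' @export
readPhenotypeTSV <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(tab)))
    stop("phenotype TSV needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Write a complete synthetic fixture directory
#'
#' Emits `genotypes.vcf`, `phenotypes.tsv`, `annotation.bed` (0-based
#' half-open intervals planted over chosen variants, labelled with
#' transcription-factor names) and `config.yaml`. All files round-trip
#' through the package readers.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [simulationConfig()].
#' @param n_annotated number of variants to cover with BED intervals
#'   (default 5; drawn from the causal window when one is planted).
#' @return named list of file paths, invisibly.
#' @export
writeFixture <- function(dir, cfg, n_annotated = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateCohort(cfg)
  ge <- sim$ge
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                phenotype = file.path(dir, "phenotypes.tsv"),
                bed = file.path(dir, "annotation.bed"),
                config = file.path(dir, "config.yaml"))
  writeVCF(ge, paths$vcf)
  pheno <- data.frame(sample_id = colnames(ge), time = sim$survival$time,
                      event = sim$survival$event, sim$probes,
                      check.names = FALSE)
  write.table(pheno, paths$phenotype, sep = "\t", quote = FALSE,
              row.names = FALSE)
  vi <- variantInfo(ge)
  pick <- if (!is.null(cfg$causal_window)) {
    s <- cfg$causal_window[1L]; w <- cfg$causal_window[2L]
    unique(round(seq(s, s + w - 1L, length.out = min(n_annotated, w))))
  } else unique(round(seq(1L, nrow(vi), length.out = min(n_annotated, nrow(vi)))))
  labels <- rep(c("GR", "NFKB"), length.out = length(pick))
  bed <- data.frame(chrom = vi$chrom[pick], start = vi$pos[pick] - 1L,
                    end = vi$pos[pick], name = labels)
  write.table(bed, paths$bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  y <- unclass(cfg)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, paths$config)
  invisible(paths)
}

#' Read a simulation config back from YAML
#'
#' @param path YAML written by [writeFixture()].
#' @return a [simulationConfig()].
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(simulationConfig, y)
}
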
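#' Enumerate sliding windows over a variant list
#'
#' Contiguous runs of `w` consecutive markers, advanced one marker at a
#' time: `M - w + 1` windows in start order, empty (with a warning) when
#' `w > M`. Windows live in marker-index space, not base-pair space.
#'
#' @param M number of variants in the region.
#' @param w window size in markers.
#' @return an [IRanges::IRanges] of 1-based index ranges.
#' @examples
#' enumerateWindows(5, 3)  # starts 1, 2, 3
#' @export
enumerateWindows <- function(M, w) {
  if (w <= 0) stop("window size must be >= 1")
  if (M < 1) stop("need at least one variant")
  if (w > M) {
    warning("window size ", w, " exceeds variant count ", M, "; skipped")
    return(IRanges::IRanges())
  }
  IRanges::IRanges(start = seq_len(M - w + 1L), width = w)
}

#' Scan plan: which window sizes to test
#'
#' @param sizes integer window sizes; default every size from 10 to 50.
#' @param includeWholeRegion also test the whole region as one window
#'   (default `TRUE`).
#' @return a `ScanPlan` object.
#' @export
scanPlan <- function(sizes = 10:50, includeWholeRegion = TRUE) {
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L)) stop("window sizes must be >= 1")
  new("ScanPlan", window_sizes = sizes,
      include_whole_region = isTRUE(includeWholeRegion))
}

#' @rdname scanPlan
#' @export
setClass("ScanPlan", representation(window_sizes = "integer",
                                    include_whole_region = "logical"))

#' @export
setMethod("show", "ScanPlan", function(object) {
  cat("ScanPlan:", length(object@window_sizes), "window sizes [",
      min(object@window_sizes), "..", max(object@window_sizes), "]",
      if (object@include_whole_region) "+ whole region", "\n")
  invisible(object)
})

#' Read a scan plan from YAML
#'
#' Recognized keys: `window_sizes: [min, max]` (or an explicit list) and
#' `include_whole_region: true/false`.
#'
#' @param path YAML file path.
#' @return a `ScanPlan`.
#' @export
readScanPlan <- function(path) {
  y <- yaml::read_yaml(path)
  sizes <- if (is.null(y$window_sizes)) 10:50
           else if (length(y$window_sizes) == 2L)
             seq(y$window_sizes[[1L]], y$window_sizes[[2L]])
           else unlist(y$window_sizes)
  inc <- if (is.null(y$include_whole_region)) TRUE else y$include_whole_region
  scanPlan(sizes, inc)
}

# Materialize every window of a plan for M variants: data.frame with start,
# size, group (one id per window size; the whole region is its own group
# unless M already is a planned size).
.planWindows <- function(plan, M) {
  sizes <- plan@window_sizes[plan@window_sizes <= M]
  if (length(sizes) < length(plan@window_sizes))
    warning("dropping window sizes larger than the ", M, "-variant region")
  out <- do.call(rbind, lapply(seq_along(sizes), function(k) {
    w <- sizes[k]
    data.frame(start = seq_len(M - w + 1L), size = w, group = k - 1L,
               whole_region = FALSE)
  }))
  if (plan@include_whole_region && !(M %in% sizes)) {
    g <- if (is.null(out)) 0L else max(out$group) + 1L
    out <- rbind(out, data.frame(start = 1L, size = M, group = g,
                                 whole_region = TRUE))
  } else if (plan@include_whole_region && (M %in% sizes)) {
    out$whole_region[out$size == M] <- TRUE
  }
  if (is.null(out) || nrow(out) == 0L)
    stop("scan plan yields no windows for M = ", M)
  out
}

#' Variant ids covered by a window
#'
#' @param ge a [GenotypeExperiment-class].
#' @param start 1-based start index into the variant list.
#' @param size window size in markers.
#' @return character vector of variant ids.
#' @export
windowVariants <- function(ge, start, size) {
  stopifnot(start >= 1L, start + size - 1L <= nVariants(ge))
  variantIds(ge)[seq(start, start + size - 1L)]
}
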
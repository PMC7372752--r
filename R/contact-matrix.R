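#' Construct a Hi-C contact matrix object
#'
#' A `ContactMatrix` holds a chromosome-level Hi-C contact map binned at a
#' fixed resolution, together with the bin-to-coordinate mapping and a gap
#' mask marking bins excluded from clustering. The matrix is interpreted as
#' the adjacency matrix of a weighted contact graph: entry `C[i, j]` is the
#' number of times bin `i` was observed in contact with bin `j`.
#'
#' @param values square, symmetric, non-negative numeric matrix of contacts.
#' @param resolution bin width in base pairs.
#' @param chrom chromosome name.
#' @param bin_start genomic coordinate (0-based) of the left edge of bin 1.
#' @param gap_mask logical vector, one entry per bin; `TRUE` marks a gap bin
#'   that is removed before clustering. Defaults to no gaps.
#'
#' @return An object of class `ContactMatrix`: a list with elements
#'   `chrom`, `resolution`, `bin_start`, `values`, and `gap_mask`.
#'
#' @examples
#' cm <- contact_matrix(matrix(c(4, 2, 2, 6), 2), resolution = 10000)
#' n_bins(cm)
#' @export
contact_matrix <- function(values, resolution, chrom = "chr1",
                           bin_start = 0, gap_mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square")
  if (!is.numeric(values) || anyNA(values))
    stop("contact matrix must be numeric with no missing values")
  if (any(values < 0))
    stop("contact matrix entries must be non-negative")
  if (!isTRUE(all(values == t(values))))
    stop("contact matrix must be symmetric; refusing to symmetrize silently")
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number")
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, nrow(values))
  if (length(gap_mask) != nrow(values) || !is.logical(gap_mask))
    stop("gap_mask must be a logical vector with one entry per bin")
  dimnames(values) <- NULL
  storage.mode(values) <- "double"
  structure(
    list(chrom = as.character(chrom), resolution = as.numeric(resolution),
         bin_start = as.numeric(bin_start), values = values,
         gap_mask = gap_mask),
    class = "ContactMatrix"
  )
}

#' Number of bins in a contact matrix
#' @param cm a `ContactMatrix`.
#' @return integer bin count.
#' @export
n_bins <- function(cm) nrow(cm$values)

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins at %g bp (span %g-%g bp)\n",
              x$chrom, n_bins(x), x$resolution, x$bin_start,
              x$bin_start + n_bins(x) * x$resolution))
  cat(sprintf("  total contacts: %g; gap bins: %d (%.1f%%)\n",
              sum(x$values), sum(x$gap_mask), 100 * mean(x$gap_mask)))
  invisible(x)
}

# genomic coordinates of bin edges (0-based half-open intervals)
bin_start_bp <- function(cm, bin) cm$bin_start + (bin - 1) * cm$resolution
bin_end_bp <- function(cm, bin) cm$bin_start + bin * cm$resolution

#' Flag low-coverage gap bins
#'
#' Gap regions are stretches of bins with no callable TAD structure: a
#' centromere, an unsequenced region, or poorly organized chromatin. Bins
#' whose marginal contact sum is at or below `coverage_threshold` times the
#' median non-zero marginal are flagged. Flagged runs overlapping a supplied
#' centromere interval are classed `"centromeric"`, all others `"other"`.
#'
#' @param cm a `ContactMatrix`.
#' @param coverage_threshold fraction in `[0, 1)`; the default `0` flags only
#'   bins with zero marginal contact sum.
#' @param centromeres optional `data.frame` with columns `start`, `end`
#'   (genomic bp, 0-based half-open) marking centromeric intervals.
#' @return A `GapReport`: list with `gap_mask` (logical per bin), `gap_runs`
#'   (`data.frame` of `start_bin`, `end_bin`, `class`), and `gap_fraction`.
#' @seealso [apply_gap_mask()] to stamp the mask onto the matrix object.
#' @export
find_gap_bins <- function(cm, coverage_threshold = 0, centromeres = NULL) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (coverage_threshold < 0 || coverage_threshold >= 1)
    stop("coverage_threshold must lie in [0, 1)")
  marg <- rowSums(cm$values)
  nz <- marg[marg > 0]
  cut <- if (length(nz)) coverage_threshold * stats::median(nz) else 0
  mask <- marg <= cut
  runs <- mask_runs(mask)
  cls <- character(nrow(runs))
  if (nrow(runs)) {
    cls[] <- "other"
    if (!is.null(centromeres) && nrow(centromeres)) {
      rs <- bin_start_bp(cm, runs$start_bin)
      re <- bin_end_bp(cm, runs$end_bin)
      for (i in seq_len(nrow(runs))) {
        hit <- any(centromeres$start < re[i] & centromeres$end > rs[i])
        if (hit) cls[i] <- "centromeric"
      }
    }
  }
  runs$class <- cls
  structure(list(gap_mask = mask, gap_runs = runs,
                 gap_fraction = mean(mask)),
            class = "GapReport")
}

#' @export
print.GapReport <- function(x, ...) {
  cat(sprintf("GapReport: %.1f%% of bins flagged in %d run(s)\n",
              100 * x$gap_fraction, nrow(x$gap_runs)))
  if (nrow(x$gap_runs)) print(x$gap_runs)
  invisible(x)
}

mask_runs <- function(mask) {
  if (!any(mask))
    return(data.frame(start_bin = integer(), end_bin = integer()))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_bin = starts[keep], end_bin = ends[keep])
}

#' Apply a gap report or mask to a contact matrix
#'
#' @param cm a `ContactMatrix`.
#' @param gaps a `GapReport` from [find_gap_bins()] or a logical vector.
#' @return The `ContactMatrix` with `gap_mask` replaced.
#' @export
apply_gap_mask <- function(cm, gaps) {
  stopifnot(inherits(cm, "ContactMatrix"))
  mask <- if (inherits(gaps, "GapReport")) gaps$gap_mask else gaps
  if (!is.logical(mask) || length(mask) != n_bins(cm))
    stop("gap mask must be logical with one entry per bin")
  cm$gap_mask <- mask
  cm
}
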
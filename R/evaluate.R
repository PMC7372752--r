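as_boundary_coords <- function(x) {
  if (inherits(x, "BoundarySet")) return(as.numeric(x$coord_bp))
  if (inherits(x, "TADSet")) return(tad_boundaries(x))
  as.numeric(x)
}

#' Jaccard similarity of two TAD boundary sets
#'
#' Without a flank, boundaries are snapped to the nearest resolution bin
#' edge and compared as sets: `J = |A intersect B| / |A union B|`. With a
#' flank, each
#' boundary becomes the interval `[x - flank_bp, x + flank_bp]`; matches
#' are found by greedy nearest-distance one-to-one pairing of overlapping
#' intervals (absorbing off-by-one bin calls), and
#' `J = matches / (|A| + |B| - matches)`. Two empty sets have similarity 1.
#'
#' @param a,b boundary sets: numeric vectors of boundary coordinates (bp),
#'   `BoundarySet`, or `TADSet` objects.
#' @param resolution bin width in bp used for snapping.
#' @param flank_bp optional flank half-width in bp (e.g. 50000).
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard_boundaries <- function(a, b, resolution, flank_bp = NULL) {
  a <- as_boundary_coords(a)
  b <- as_boundary_coords(b)
  if (!length(a) && !length(b)) return(1)
  if (is.null(flank_bp)) {
    ba <- unique(round(a / resolution))
    bb <- unique(round(b / resolution))
    return(length(intersect(ba, bb)) / length(union(ba, bb)))
  }
  matches <- greedy_interval_matches(a, b, flank_bp)
  matches / (length(a) + length(b) - matches)
}

# one-to-one greedy pairing of boundaries whose flanked intervals overlap,
# nearest pairs first
greedy_interval_matches <- function(a, b, flank_bp) {
  a <- sort(unique(a)); b <- sort(unique(b))
  if (!length(a) || !length(b)) return(0L)
  pairs <- expand.grid(i = seq_along(a), j = seq_along(b))
  pairs$dist <- abs(a[pairs$i] - b[pairs$j])
  pairs <- pairs[pairs$dist <= 2 * flank_bp, , drop = FALSE]
  pairs <- pairs[order(pairs$dist, pairs$i, pairs$j), , drop = FALSE]
  used_a <- logical(length(a)); used_b <- logical(length(b))
  matches <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      matches <- matches + 1L
    }
  }
  matches
}

#' Cross-resolution (modified) Jaccard similarity
#'
#' Boundary sets called at different resolutions cannot agree exactly on
#' coordinates even when they mark the same boundaries. Both sets are
#' snapped to the coarser of the two bin grids before the
#' set Jaccard is computed, so agreement is judged independent of
#' resolution. Resolutions must be commensurate (the coarser a multiple of
#' the finer).
#'
#' @param a,b boundary sets as in [jaccard_boundaries()].
#' @param resolution_a,resolution_b bin widths (bp) at which `a` and `b`
#'   were called.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
modified_jaccard <- function(a, resolution_a, b, resolution_b) {
  coarse <- max(resolution_a, resolution_b)
  fine <- min(resolution_a, resolution_b)
  if (coarse %% fine != 0)
    stop("resolutions ", fine, " and ", coarse, " share no common grid")
  jaccard_boundaries(as_boundary_coords(a), as_boundary_coords(b),
                     resolution = coarse)
}

#' Perturb a contact matrix with noise, sparsity, or downsampling
#'
#' Reproduces the three degradation regimes used to benchmark TAD-calling
#' robustness:
#' \describe{
#'   \item{`noise`}{a uniformly random fraction `level` of upper-triangle
#'     cells (diagonal included) has `constant` added.}
#'   \item{`sparsity`}{a fraction `level` of upper-triangle cells is set
#'     to zero.}
#'   \item{`downsample`}{contacts are treated as a multinomial over cells
#'     and `round(level * total)` contacts are resampled with replacement
#'     proportional to the original counts, emulating reduced sequencing
#'     depth (`level` is the fraction of contacts kept).}
#' }
#' All modes modify the upper triangle and mirror it, so the output is
#' symmetric; with a fixed `seed` the output is reproducible, and the
#' caller's RNG state is left untouched.
#'
#' @param cm a `ContactMatrix`.
#' @param mode `"noise"`, `"sparsity"`, or `"downsample"`.
#' @param level fraction in `[0, 1]`: cells modified (noise, sparsity) or
#'   contacts kept (downsample). `level = 0` returns the matrix unchanged
#'   for noise/sparsity and empties it for downsampling.
#' @param constant value added in noise mode (default 2).
#' @param seed optional RNG seed.
#' @return A perturbed `ContactMatrix`.
#' @export
perturb_matrix <- function(cm, mode = c("noise", "sparsity", "downsample"),
                           level, constant = 2, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "ContactMatrix"))
  if (level < 0 || level > 1) stop("level must lie in [0, 1]")
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  v <- cm$values
  ut <- which(upper.tri(v, diag = TRUE))
  if (mode == "noise" || mode == "sparsity") {
    k <- round(level * length(ut))
    if (k > 0) {
      sel <- sample(ut, k)
      if (mode == "noise") v[sel] <- v[sel] + constant else v[sel] <- 0
    }
  } else {
    counts <- v[ut]
    total <- sum(counts)
    n_keep <- round(level * total)
    v[ut] <- if (n_keep > 0 && total > 0)
      as.numeric(stats::rmultinom(1, n_keep, prob = counts))
    else 0
  }
  lo <- lower.tri(v)
  v[lo] <- t(v)[lo]
  cm$values <- v
  cm
}

# Seed the RNG and return a restore function for on.exit(); with seed =
# NULL both the seeding and the restore are no-ops, so the caller's RNG
# stream is consumed as usual.
push_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible()
  }
}

#' Permutation test for annotation enrichment at TAD boundaries
#'
#' Counts annotation intervals overlapping the `[x - flank_bp,
#' x + flank_bp]` region around each boundary and compares the mean count
#' per boundary against a null in which the same number of boundaries is
#' placed uniformly at random on the non-gap bins of the chromosome, `B`
#' times. P-values use the add-one convention, so they are bounded below
#' by `1 / (B + 1)` and never exactly zero.
#'
#' @param boundaries boundary coordinates (bp): numeric vector,
#'   `BoundarySet`, or `TADSet`.
#' @param annotations annotation intervals: a `GRanges`, a `data.frame`
#'   with `start` / `end` columns (bp), or a BED file path.
#' @param chrom_length chromosome length in bp.
#' @param resolution bin width in bp (defines the null placement grid).
#' @param gap_mask optional logical per bin; `TRUE` bins are excluded from
#'   null placement.
#' @param B number of permutations (default 1000).
#' @param flank_bp flank half-width around each boundary (default 50000).
#' @param annotation_name label carried into the result.
#' @param seed optional RNG seed.
#' @return An `EnrichmentResult`: list with `annotation_name`,
#'   `observed_count` (mean annotations per flanked boundary),
#'   `null_counts` (length `B`), `p_enrich`, `p_deplete`, and `flank_bp`.
#' @export
permutation_enrichment <- function(boundaries, annotations, chrom_length,
                                   resolution, gap_mask = NULL, B = 1000,
                                   flank_bp = 50000,
                                   annotation_name = "annotation",
                                   seed = NULL) {
  if (B < 1) stop("B must be at least 1")
  x <- as_boundary_coords(boundaries)
  if (!length(x)) stop("no boundaries supplied")
  ann <- as_annotation_ranges(annotations)
  n_bin <- floor(chrom_length / resolution)
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, n_bin)
  open_bins <- which(!gap_mask)
  if (!length(open_bins)) stop("no non-gap bins to permute over")
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  obs <- mean(flank_counts(x, ann, flank_bp))
  nb <- length(x)
  null_bins <- matrix(sample(open_bins, B * nb, replace = TRUE), nrow = B)
  null_coords <- null_bins * resolution   # rightmost point of each bin
  cnt <- flank_counts(as.vector(t(null_coords)), ann, flank_bp)
  null_counts <- rowMeans(matrix(cnt, nrow = B, byrow = TRUE))
  structure(list(
    annotation_name = annotation_name,
    observed_count = obs,
    null_counts = null_counts,
    p_enrich = (1 + sum(null_counts >= obs)) / (1 + B),
    p_deplete = (1 + sum(null_counts <= obs)) / (1 + B),
    flank_bp = flank_bp), class = "EnrichmentResult")
}

as_annotation_ranges <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- read_bed_intervals(annotations)
  if (methods::is(annotations, "GRanges"))
    return(GenomicRanges::ranges(annotations))
  if (methods::is(annotations, "IRanges")) return(annotations)
  if (is.data.frame(annotations))
    return(IRanges::IRanges(start = annotations$start + 1L,
                            end = annotations$end))
  stop("annotations must be a GRanges, a data.frame, or a BED path")
}

flank_counts <- function(coords, ann, flank_bp) {
  flanks <- IRanges::IRanges(start = pmax(1, coords - flank_bp),
                             end = coords + flank_bp)
  IRanges::countOverlaps(flanks, ann)
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: %s\n  %.3f annotations per flanked boundary (flank %g bp)\n  p_enrich = %.4g, p_deplete = %.4g (B = %d)\n",
    x$annotation_name, x$observed_count, x$flank_bp, x$p_enrich,
    x$p_deplete, length(x$null_counts)))
  invisible(x)
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom. A single p-value is returned unchanged.
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @param zero_floor optional floor applied to zero p-values (e.g.
#'   `1 / (B + 1)` for permutation p-values); with the default `NULL`,
#'   zeros are an error.
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values, zero_floor = NULL) {
  p <- as.numeric(p_values)
  if (!length(p)) stop("no p-values supplied")
  if (any(p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (any(p == 0)) {
    if (is.null(zero_floor)) stop("p-value of 0; supply zero_floor")
    p[p == 0] <- zero_floor
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
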
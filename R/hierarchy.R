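#' Construct a TAD set
#'
#' A `TADSet` is a data frame of TAD records with one row per TAD:
#' `chrom`, `start_bin` / `end_bin` (inclusive 1-based bin span),
#' `start_bp` / `end_bp` (0-based half-open genomic coordinates), and
#' `level` (hierarchy depth: 1 = primary, 2 = secondary, 3 = tertiary,
#' ...). Records at depth `d + 1` must each be contained in exactly one
#' depth-`d` record, and records within a depth must be disjoint.
#'
#' @param chrom chromosome name (recycled).
#' @param start_bin,end_bin inclusive bin spans.
#' @param start_bp,end_bp genomic coordinates (0-based half-open).
#' @param level integer hierarchy depth per record.
#' @return A `TADSet` (also a `data.frame`), sorted by level then start.
#' @export
tad_set <- function(chrom = character(), start_bin = integer(),
                    end_bin = integer(), start_bp = numeric(),
                    end_bp = numeric(), level = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start_bin = as.integer(start_bin),
                   end_bin = as.integer(end_bin),
                   start_bp = as.numeric(start_bp),
                   end_bp = as.numeric(end_bp),
                   level = as.integer(level))
  df <- df[order(df$level, df$start_bin), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("TADSet", "data.frame")
  validate_tad_set(df)
  df
}

validate_tad_set <- function(tads) {
  if (!nrow(tads)) return(invisible(tads))
  if (any(tads$end_bin < tads$start_bin))
    stop("TAD with end before start")
  for (d in sort(unique(tads$level))) {
    at <- tads[tads$level == d, ]
    at <- at[order(at$start_bin), ]
    if (nrow(at) > 1 && any(at$start_bin[-1] <= at$end_bin[-nrow(at)]))
      stop("overlapping TADs at level ", d)
    up <- tads[tads$level == d - 1, ]
    if (d > 1 && nrow(up)) {
      for (i in seq_len(nrow(at))) {
        inside <- up$start_bin <= at$start_bin[i] &
          up$end_bin >= at$end_bin[i]
        if (sum(inside) != 1)
          stop("level-", d, " TAD not nested in exactly one level-",
               d - 1, " TAD")
      }
    }
  }
  invisible(tads)
}

#' @export
print.TADSet <- function(x, ...) {
  cat(sprintf("TADSet: %d TAD(s), max depth %s\n", nrow(x),
              if (nrow(x)) max(x$level) else 0))
  print.data.frame(x, ...)
  invisible(x)
}

spans_to_tads <- function(cm, start_bin, end_bin, level) {
  tad_set(chrom = rep(cm$chrom, length(start_bin)),
          start_bin = start_bin, end_bin = end_bin,
          start_bp = bin_start_bp(cm, start_bin),
          end_bp = bin_end_bp(cm, end_bin),
          level = rep(as.integer(level), length(start_bin)))
}

# Z-score cut positions for one (gap-free) submatrix; local coordinates.
# Gaps are floored at cfg$gap_floor before taking logs: zero and
# numerically-tied gaps all land on the floor and carry no signal, while
# any structural gap sits far above it. If no gap clears the floor, or the
# log gaps have zero spread, there is no structure to split.
zscore_cuts <- function(vals, cfg) {
  n <- nrow(vals)
  if (n < 2 * cfg$min_tad_bins) return(integer())
  L <- build_laplacian(vals)
  proj <- project_eigenvectors(L, min(cfg$k, n))
  D <- proj$gap_vector
  if (!any(D > cfg$gap_floor)) return(integer())
  lg <- log(pmax(D, cfg$gap_floor))
  sdl <- stats::sd(lg)
  if (!is.finite(sdl) || sdl == 0) return(integer())
  z <- (lg - mean(lg)) / sdl
  hits <- which(z > cfg$z_threshold)
  if (!length(hits)) return(integer())
  # greedy admission in decreasing z order; a cut is kept only if every
  # resulting segment stays >= min_tad_bins wide
  hits <- hits[order(-z[hits], hits)]
  accepted <- integer()
  for (h in hits) {
    cut <- h + 1L
    lo <- max(c(1L, accepted[accepted <= cut]))
    hi <- min(c(n + 1L, accepted[accepted > cut]))
    if (cut - lo >= cfg$min_tad_bins && hi - cut >= cfg$min_tad_bins)
      accepted <- c(accepted, cut)
  }
  sort(accepted)
}

#' Detect sub-TAD boundaries inside one TAD
#'
#' The TAD's submatrix is treated as a standalone contact matrix (no
#' sliding window). Its eigenvector gap vector `D` is converted to
#' Z-scores of `log(D)` — eigenvector gaps are approximately lognormal —
#' and every position with `z > z_threshold` becomes a sub-boundary,
#' unless it would create a sub-TAD narrower than `min_tad_bins`. A TAD
#' narrower than `2 * min_tad_bins`, or one whose gaps show no spread,
#' returns no boundaries.
#'
#' @param cm a `ContactMatrix`.
#' @param tad a single TAD: one row of a `TADSet` or a list with
#'   `start_bin` and `end_bin`.
#' @param cfg a [window_config()]; `cfg$z_threshold` sets the cutoff.
#' @return Integer vector of boundary positions (chromosome bin index of
#'   the first bin of each right-hand sub-TAD), possibly empty.
#' @export
split_tad <- function(cm, tad, cfg) {
  stopifnot(inherits(cm, "ContactMatrix"))
  bins <- tad_live_bins(cm, tad$start_bin, tad$end_bin)
  if (length(bins) < 2 * cfg$min_tad_bins) return(integer())
  cuts <- zscore_cuts(cm$values[bins, bins, drop = FALSE], cfg)
  bins[cuts]
}

tad_live_bins <- function(cm, start_bin, end_bin) {
  bins <- seq.int(start_bin, end_bin)
  bins[!cm$gap_mask[bins] & rowSums(cm$values[bins, , drop = FALSE]) > 0]
}

#' Build the TAD hierarchy by recursive splitting
#'
#' Applies [split_tad()] to every primary TAD; each significant split
#' partitions the parent into sub-TADs recorded one level deeper. The
#' recursion continues per branch until the TAD is too small to hold two
#' minimum-width sub-TADs, no significant boundary remains, or
#' `cfg$max_levels` is reached.
#'
#' @param cm a `ContactMatrix`.
#' @param primaries a `TADSet` of depth-1 records, e.g. from
#'   [call_tads()].
#' @param cfg a [window_config()].
#' @return A `TADSet` containing the primaries plus all sub-TADs.
#' @export
build_hierarchy <- function(cm, primaries, cfg) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (!nrow(primaries)) return(primaries)
  if (any(primaries$level != 1))
    stop("primaries must all be level-1 records")
  out <- list(primaries)
  frontier <- primaries
  depth <- 1L
  while (depth < cfg$max_levels && nrow(frontier)) {
    kids_s <- kids_e <- integer()
    for (i in seq_len(nrow(frontier))) {
      tad <- frontier[i, ]
      bins <- tad_live_bins(cm, tad$start_bin, tad$end_bin)
      if (length(bins) < 2 * cfg$min_tad_bins) next
      cuts <- zscore_cuts(cm$values[bins, bins, drop = FALSE], cfg)
      if (!length(cuts)) next
      edges <- c(1L, cuts, length(bins) + 1L)
      kids_s <- c(kids_s, bins[edges[-length(edges)]])
      kids_e <- c(kids_e, bins[edges[-1] - 1L])
    }
    if (!length(kids_s)) break
    depth <- depth + 1L
    frontier <- spans_to_tads(cm, kids_s, kids_e, level = depth)
    out[[depth]] <- frontier
  }
  all <- do.call(rbind, lapply(out, as.data.frame))
  tad_set(all$chrom, all$start_bin, all$end_bin, all$start_bp, all$end_bp,
          all$level)
}

#' Call the full TAD hierarchy of a chromosome
#'
#' Convenience wrapper: [call_tads()] for the primaries, then
#' [build_hierarchy()] for the sub-TADs.
#'
#' @inheritParams call_tads
#' @return A `TADSet` with all hierarchy levels.
#' @export
call_hierarchy <- function(cm, cfg) {
  build_hierarchy(cm, call_tads(cm, cfg), cfg)
}

#' Boundary coordinates and their sharing levels
#'
#' A boundary is the rightmost point of a TAD. Boundaries belonging to a
#' single TAD are level 1; boundaries shared by two or three TADs (across
#' hierarchy depths, e.g. a primary and its last secondary ending at the
#' same coordinate) are level 2 or 3. Reported levels are capped at
#' `max_level`.
#'
#' @param tads a `TADSet`.
#' @param max_level reporting cap for the sharing level (default 3).
#' @return A `BoundarySet`: data frame with `coord_bp` (unique, sorted)
#'   and `level`.
#' @export
boundary_levels <- function(tads, max_level = 3) {
  if (!nrow(tads)) {
    bs <- data.frame(coord_bp = numeric(), level = integer())
  } else {
    tab <- table(tads$end_bp)
    bs <- data.frame(coord_bp = as.numeric(names(tab)),
                     level = pmin(as.integer(tab), as.integer(max_level)))
    bs <- bs[order(bs$coord_bp), , drop = FALSE]
    rownames(bs) <- NULL
  }
  class(bs) <- c("BoundarySet", "data.frame")
  bs
}

#' @export
print.BoundarySet <- function(x, ...) {
  lv <- if (nrow(x)) paste(range(x$level), collapse = "-") else "none"
  cat(sprintf("BoundarySet: %d boundaries (levels %s)\n", nrow(x), lv))
  print.data.frame(x, ...)
  invisible(x)
}

#' Boundary coordinates of a TAD set
#'
#' @param tads a `TADSet`.
#' @param level restrict to records of these hierarchy depths
#'   (default: all).
#' @return Sorted unique numeric vector of rightmost coordinates in bp.
#' @export
tad_boundaries <- function(tads, level = NULL) {
  if (!is.null(level)) tads <- tads[tads$level %in% level, , drop = FALSE]
  sort(unique(as.numeric(tads$end_bp)))
}
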
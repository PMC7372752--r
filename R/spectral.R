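#' Configuration for the windowed spectral TAD caller
#'
#' The sliding window covers the maximum biologically plausible TAD size,
#' 2 Mb by default, so the window holds `w = window_bp / resolution` bins
#' (200 bins at 10 kb). The minimum TAD width of 5 bins bounds the number
#' of boundary candidates per window at `l = floor(w / min_tad_bins)` and
#' caps the usable resolution at `window_bp / (2 * min_tad_bins)` = 200 kb:
#' any coarser and a window could not hold two minimum-width TADs.
#'
#' @param resolution bin width in bp; must not exceed the derived cap.
#' @param window_bp maximum TAD size in bp (default 2,000,000).
#' @param min_tad_bins minimum TAD width in bins (default 5).
#' @param n_eigenvectors number of leading eigenvectors `k` used for the
#'   unit-circle projection (default 2).
#' @param organization_threshold minimum mean silhouette for a window to be
#'   considered organized; windows scoring below it yield no TADs and are
#'   treated as gap-like regions (default 0.15).
#' @param z_threshold Z-score cutoff on log eigenvector gaps used for
#'   sub-TAD detection (default 2).
#' @param max_levels deepest hierarchy level reported (default 3:
#'   primary, secondary, tertiary).
#' @param gap_floor numerical floor for eigenvector gaps before taking
#'   logs; gaps at or below it are treated as exact ties (default 1e-10).
#' @param first_pass how primary TADs are found: `"silhouette"` (windowed,
#'   silhouette-maximizing; the default) or `"zscore"` (one whole-matrix
#'   pass of the log-gap Z-score rule used for sub-TADs).
#' @return A `WindowConfig` list; `w` is the window size in bins and
#'   `max_resolution` the derived resolution cap in bp.
#' @export
window_config <- function(resolution,
                          window_bp = 2e6,
                          min_tad_bins = 5,
                          n_eigenvectors = 2,
                          organization_threshold = 0.15,
                          z_threshold = 2,
                          max_levels = 3,
                          gap_floor = 1e-10,
                          first_pass = c("silhouette", "zscore")) {
  first_pass <- match.arg(first_pass)
  if (min_tad_bins < 1) stop("min_tad_bins must be >= 1")
  if (n_eigenvectors < 2) stop("at least two eigenvectors are required")
  max_resolution <- window_bp / (2 * min_tad_bins)
  if (resolution > max_resolution)
    stop(sprintf(
      "resolution %g bp exceeds the maximum of %g bp (a %g bp window must hold two TADs of %d bins)",
      resolution, max_resolution, window_bp, min_tad_bins))
  w <- as.integer(floor(window_bp / resolution))
  structure(list(resolution = resolution, window_bp = window_bp, w = w,
                 max_resolution = max_resolution,
                 min_tad_bins = as.integer(min_tad_bins),
                 k = as.integer(n_eigenvectors),
                 organization_threshold = organization_threshold,
                 z_threshold = z_threshold,
                 max_levels = as.integer(max_levels),
                 gap_floor = gap_floor,
                 first_pass = first_pass),
            class = "WindowConfig")
}

#' @export
print.WindowConfig <- function(x, ...) {
  cat(sprintf(
    "WindowConfig: %g bp bins, %g bp window = %d bins; min TAD %d bins; k = %d\n",
    x$resolution, x$window_bp, x$w, x$min_tad_bins, x$k))
  cat(sprintf("  organization threshold %.2f; z > %g; up to %d levels; first pass: %s\n",
              x$organization_threshold, x$z_threshold, x$max_levels,
              x$first_pass))
  invisible(x)
}

#' Symmetric normalized Laplacian of a contact submatrix
#'
#' Computes `D^(-1/2) C D^(-1/2)` with `D = diag(rowSums(C))`. This is an
#' affinity-normalized operator (not `I` minus it): its leading eigenvalue
#' is 1 whenever all marginals are positive, and the eigenvectors of the
#' *largest* eigenvalues carry the cluster structure.
#'
#' @param values square symmetric non-negative matrix with strictly
#'   positive marginals (gap bins must be removed beforehand).
#' @return Symmetric matrix of the same dimension.
#' @export
build_laplacian <- function(values) {
  m <- rowSums(values)
  if (any(m <= 0))
    stop("zero marginal among included bins; remove gap bins first")
  sm <- sqrt(m)
  values / outer(sm, sm)
}

#' Eigenvector projection onto the unit circle and its gap vector
#'
#' Takes the `k` eigenvectors of `L` with the largest eigenvalues, then
#' normalizes each row of the resulting `w x k` matrix to unit Euclidean
#' norm, projecting every bin onto the unit circle (for `k = 2`). The gap
#' vector holds the Euclidean distance between consecutive projected rows;
#' entry `i` is the distance between bins `i` and `i + 1`, so a large gap
#' marks a candidate TAD boundary in front of bin `i + 1`.
#'
#' Rows whose eigencomponents are all (numerically) zero cannot be
#' normalized; they are flagged in `zero_rows` and distances to or from
#' them are defined as 0. Consecutive identical rows of `L` are forced to a
#' gap of exactly 0, so that degenerate eigenspaces of block-constant
#' matrices cannot manufacture spurious gaps.
#'
#' @param L symmetric matrix, typically from [build_laplacian()].
#' @param k number of eigenvectors (must not exceed `nrow(L)`).
#' @return An `EigenProjection`: list with `eigenvalues` (length `k`,
#'   descending), `raw_vectors` (`w x k`), `unit_rows` (`w x k`, unit-norm
#'   rows), `gap_vector` (length `w - 1`, entries in `[0, 2]`), and
#'   `zero_rows` (logical).
#' @export
project_eigenvectors <- function(L, k = 2) {
  n <- nrow(L)
  if (k > n) stop("k must not exceed the matrix dimension")
  e <- eigen(L, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(V^2))
  zero <- norms < 1e-12
  Z <- V / ifelse(zero, 1, norms)
  Z[zero, ] <- 0
  gap <- sqrt(rowSums((Z[-1, , drop = FALSE] - Z[-n, , drop = FALSE])^2))
  gap[zero[-n] | zero[-1]] <- 0
  # identical consecutive rows of L admit no boundary between them, no
  # matter which basis the eigensolver picked inside a degenerate eigenspace
  scale <- max(abs(L))
  same <- which(rowSums(abs(L[-1, , drop = FALSE] -
                              L[-n, , drop = FALSE])) <= 1e-12 * scale * n)
  gap[same] <- 0
  structure(list(eigenvalues = e$values[seq_len(k)], raw_vectors = V,
                 unit_rows = Z, gap_vector = gap, zero_rows = zero),
            class = "EigenProjection")
}

#' Candidate TAD boundaries from the eigenvector gap vector
#'
#' Returns the positions of the `l = floor(w / min_tad_bins)` largest gap
#' values; `l + 1` is then the maximum number of TADs a window can hold.
#' Ties are broken toward the left-most position. Positions are reported as
#' the index of the first bin of the right-hand cluster, and are returned
#' in decreasing gap order (rank order), which downstream partition scoring
#' relies on.
#'
#' @param gap_vector gap vector of length `w - 1` from
#'   [project_eigenvectors()].
#' @param w window size in bins; defaults to `length(gap_vector) + 1`.
#' @param min_tad_bins minimum TAD width in bins.
#' @return Integer vector of candidate cut positions in rank order.
#' @export
candidate_boundaries <- function(gap_vector, w = length(gap_vector) + 1L,
                                 min_tad_bins = 5) {
  if (w < 2 * min_tad_bins)
    stop("window of ", w, " bins cannot hold two TADs of ",
         min_tad_bins, " bins")
  if (length(gap_vector) != w - 1)
    stop("gap_vector must have length w - 1")
  l <- floor(w / min_tad_bins)
  ord <- order(-gap_vector, seq_along(gap_vector))
  utils::head(ord, l) + 1L
}

#' Silhouette-maximizing contiguous partition of a window
#'
#' For each candidate cluster count `m` in `2 .. l + 1`, the window is cut
#' at the `m - 1` highest-ranked candidate boundaries (re-sorted by
#' position) and scored by the mean per-cluster silhouette under the
#' contact distance `d[i, j] = 1 / (C[i, j] + 1)` (so unobserved pairs are
#' at distance 1). For cluster `i`, `a_i` is the mean within-cluster
#' distance, `b_i` the mean distance to the nearest other cluster, and
#' `s_i = (b_i - a_i) / max(a_i, b_i)`; maximizing the mean selects
#' compact, well-separated clusters. Singleton clusters score 0, the usual
#' silhouette convention. Ties go to the smaller `m`.
#'
#' @param values contact submatrix of the window (raw counts).
#' @param candidates candidate cut positions in rank order, from
#'   [candidate_boundaries()].
#' @return A `PartitionScore`: list with `m`, `boundaries` (sorted cut
#'   positions), `per_cluster_s`, `a`, `b`, and `mean_s`.
#' @export
silhouette_partition <- function(values, candidates) {
  n <- nrow(values)
  candidates <- candidates[candidates >= 2 & candidates <= n]
  if (!length(candidates))
    stop("no candidate yields two valid clusters")
  d <- 1 / (values + 1)
  best <- NULL
  for (m in 2:(length(candidates) + 1)) {
    cuts <- sort(candidates[seq_len(m - 1)])
    sc <- score_partition(d, cuts)
    if (is.null(best) || sc$mean_s > best$mean_s + 1e-12) {
      best <- sc
      best$m <- m
    }
  }
  structure(best[c("m", "boundaries", "per_cluster_s", "a", "b", "mean_s")],
            class = "PartitionScore")
}

# cluster-level silhouette of a contiguous partition given distance matrix
score_partition <- function(d, cuts) {
  n <- nrow(d)
  edges <- c(1L, cuts, n + 1L)
  m <- length(edges) - 1L
  segs <- lapply(seq_len(m), function(i) edges[i]:(edges[i + 1] - 1L))
  a <- b <- s <- numeric(m)
  for (i in seq_len(m)) {
    si <- segs[[i]]
    b[i] <- min(vapply(seq_len(m)[-i],
                       function(j) mean(d[si, segs[[j]], drop = FALSE]),
                       numeric(1)))
    if (length(si) < 2) {
      # singleton clusters score 0 (the usual silhouette convention);
      # otherwise a = 0 would hand them a perfect score and model
      # selection would favour shattering windows into single bins
      a[i] <- 0
      s[i] <- 0
    } else {
      dd <- d[si, si]
      a[i] <- sum(dd[upper.tri(dd)]) / choose(length(si), 2)
      s[i] <- if (max(a[i], b[i]) == 0) 0
              else (b[i] - a[i]) / max(a[i], b[i])
    }
  }
  list(boundaries = cuts, per_cluster_s = s, a = a, b = b, mean_s = mean(s))
}

# Partition one window of a (gap-free) contact matrix.
# vals: window submatrix. Returns spans in window-local coordinates.
window_partition <- function(vals, cfg) {
  nw <- nrow(vals)
  live <- rowSums(vals) > 0
  empty <- list(spans = cbind(start = integer(), end = integer()),
                organized = FALSE, score = NULL)
  if (sum(live) < 2 * cfg$min_tad_bins) return(empty)
  v <- vals[live, live, drop = FALSE]
  idx <- which(live)
  L <- build_laplacian(v)
  proj <- project_eigenvectors(L, min(cfg$k, nrow(v)))
  cand <- candidate_boundaries(proj$gap_vector, nrow(v), cfg$min_tad_bins)
  score <- silhouette_partition(v, cand)
  if (score$mean_s < cfg$organization_threshold)
    return(list(spans = empty$spans, organized = FALSE, score = score))
  edges <- c(1L, score$boundaries, nrow(v) + 1L)
  starts <- edges[-length(edges)]
  ends <- edges[-1] - 1L
  keep <- (ends - starts + 1L) >= cfg$min_tad_bins
  spans <- cbind(start = idx[starts[keep]], end = idx[ends[keep]])
  list(spans = spans, organized = TRUE, score = score)
}

#' Call TADs within a single window
#'
#' Composes the full per-window pipeline (Laplacian, eigenvector
#' projection, gap candidates, silhouette partition) on the window starting
#' at `start_bin` of the gap-free matrix, then converts clusters to TAD
#' records, discarding any narrower than `min_tad_bins`. Windows whose best
#' mean silhouette falls below the organization threshold are declared
#' unorganized and yield no TADs.
#'
#' @param cm a `ContactMatrix`; its gap bins are removed before windowing,
#'   so `start_bin` indexes the gap-free matrix.
#' @param start_bin first bin of the window (gap-free indexing); the window
#'   spans `cfg$w` bins and is truncated at the end of the matrix.
#' @param cfg a [window_config()].
#' @return List with `tads` (a `TADSet` of depth-1 records, possibly
#'   empty), `organized` (logical), and `score` (the winning
#'   `PartitionScore`, or `NULL`).
#' @export
call_window <- function(cm, start_bin, cfg) {
  stopifnot(inherits(cm, "ContactMatrix"), inherits(cfg, "WindowConfig"))
  kept <- which(!cm$gap_mask)
  nk <- length(kept)
  if (start_bin < 1 || start_bin > nk)
    stop("start_bin outside the gap-free matrix")
  end_bin <- min(start_bin + cfg$w - 1L, nk)
  win <- kept[start_bin:end_bin]
  res <- window_partition(cm$values[win, win, drop = FALSE], cfg)
  spans <- res$spans
  tads <- spans_to_tads(cm, win[spans[, "start"]], win[spans[, "end"]],
                        level = 1L)
  list(tads = tads, organized = res$organized, score = res$score)
}

#' Call primary TADs across a chromosome
#'
#' Sweeps windows of `cfg$w` bins along the diagonal of the gap-free
#' matrix. After each window all detected TADs except the last are
#' committed and the next window starts at the first bin of the last TAD,
#' which is re-called with fuller context (the final TAD of a window may be
#' truncated by the window edge). If a window yields fewer than two TADs,
#' or fails to advance, the window moves forward by `w - min_tad_bins`
#' bins, which guarantees progress. A chromosome tail consisting of a
#' single TAD is a special case: the final window then holds one uniform
#' block that silhouette cannot split, so if the previous window detected
#' a TAD starting exactly at the final window's start, that TAD is
#' committed extended to the end of the matrix. Gap bins are deleted
#' before clustering
#' and coordinates are mapped back afterwards, so a TAD may span a
#' (non-centromeric) gap but no TAD is ever reported inside one.
#'
#' With `cfg$first_pass = "zscore"` the whole gap-free matrix is segmented
#' in one pass by the log-gap Z-score rule of [split_tad()] instead.
#'
#' @param cm a `ContactMatrix` (set `gap_mask` first, e.g. via
#'   [find_gap_bins()] and [apply_gap_mask()], if the matrix has gaps).
#' @param cfg a [window_config()]; the configuration fixes the resolution,
#'   which must match `cm$resolution`.
#' @return A `TADSet` of disjoint, sorted primary TADs.
#' @export
call_tads <- function(cm, cfg) {
  stopifnot(inherits(cm, "ContactMatrix"), inherits(cfg, "WindowConfig"))
  if (cm$resolution != cfg$resolution)
    stop("configuration resolution does not match the matrix")
  kept <- which(!cm$gap_mask & rowSums(cm$values) > 0)
  nk <- length(kept)
  if (nk < 2 * cfg$min_tad_bins)
    return(tad_set(cm$chrom))
  if (cfg$first_pass == "zscore")
    return(zscore_first_pass(cm, kept, cfg))
  vals <- cm$values[kept, kept, drop = FALSE]
  w <- cfg$w
  committed_s <- committed_e <- integer()
  last_end <- 0L
  s <- 1L
  pending <- NULL   # last TAD of the previous window, awaiting re-call
  repeat {
    e <- min(s + w - 1L, nk)
    res <- window_partition(vals[s:e, s:e, drop = FALSE], cfg)
    spans <- res$spans
    if (nrow(spans)) {
      spans[, "start"] <- spans[, "start"] + s - 1L
      spans[, "end"] <- spans[, "end"] + s - 1L
    }
    final_window <- e >= nk
    if (final_window && !nrow(spans) && !is.null(pending) &&
        pending[1] == s) {
      # the tail is a single TAD: the previous window found a boundary at
      # s, and the final window shows no further structure to cut, so the
      # pending TAD runs to the end of the matrix
      spans <- cbind(start = pending[1], end = nk)
    }
    commit_n <- if (final_window) nrow(spans)
                else if (nrow(spans) >= 2) nrow(spans) - 1L
                else nrow(spans)
    if (commit_n > 0) {
      for (i in seq_len(commit_n)) {
        if (spans[i, "start"] > last_end) {
          committed_s <- c(committed_s, spans[i, "start"])
          committed_e <- c(committed_e, spans[i, "end"])
          last_end <- spans[i, "end"]
        }
      }
    }
    if (final_window) break
    if (nrow(spans) >= 2) {
      pending <- c(spans[nrow(spans), "start"], spans[nrow(spans), "end"])
    } else {
      pending <- NULL
    }
    s_new <- if (nrow(spans) >= 2) spans[nrow(spans), "start"]
             else s + (w - cfg$min_tad_bins)
    if (s_new <= s) s_new <- s + (w - cfg$min_tad_bins)   # stall guard
    # never re-enter territory that is already committed
    if (s_new <= last_end) s_new <- last_end + 1L
    if (s_new > nk) break
    s <- as.integer(s_new)
  }
  spans_to_tads(cm, kept[committed_s], kept[committed_e], level = 1L)
}

zscore_first_pass <- function(cm, kept, cfg) {
  vals <- cm$values[kept, kept, drop = FALSE]
  cuts <- zscore_cuts(vals, cfg)
  if (!length(cuts)) return(tad_set(cm$chrom))
  edges <- c(1L, cuts, nrow(vals) + 1L)
  spans_to_tads(cm, kept[edges[-length(edges)]], kept[edges[-1] - 1L],
                level = 1L)
}
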
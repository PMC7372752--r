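#' Specify a synthetic hierarchical block contact matrix
#'
#' Defines a block-structured chromosome in which TADs appear as
#' contact-enriched diagonal blocks, optionally nested. Blocks are given
#' either as a flat numeric vector of widths (a single level) or as a
#' nested list of nodes `list(width =, children =)` whose children tile
#' their parent exactly.
#'
#' The expected contact intensity between bins `i` and `j` depends on the
#' number of blocks `d` (across all levels) containing both:
#' `E[C_ij] = intensity(d)`. By default intensities follow the geometric
#' ladder `between * (within / between)^d`, so each extra shared level
#' multiplies enrichment by the same within/between contrast; an explicit
#' `level_intensities` vector (`d = 0, 1, 2, ...`) overrides the ladder,
#' which is how fixtures with deliberately milder sub-TAD contrast are
#' built. An optional power-law distance decay `(|i - j| + 1)^-decay`
#' multiplies the expectation, and `count_noise = "poisson"` replaces the
#' expectation with a Poisson draw.
#'
#' @param blocks numeric widths or nested list of
#'   `list(width =, children =)` nodes; widths are in bins and every block
#'   must be at least `min_block` wide.
#' @param within_intensity,between_intensity expected contacts within the
#'   deepest shared block / between top-level blocks (a contrast of at
#'   least 2, ideally 5, keeps blocks well separated).
#' @param level_intensities optional numeric vector of expected intensities
#'   for shared depth 0, 1, 2, ...; overrides the geometric ladder.
#' @param decay_exponent optional power-law distance-decay exponent.
#' @param count_noise `"none"` (expected values, deterministic) or
#'   `"poisson"`.
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @param seed optional RNG seed for the Poisson draw.
#' @param min_block minimum block width in bins (default 5, the minimum
#'   TAD size).
#' @return A `SimSpec` list, input to [simulate_matrix()].
#' @export
sim_spec <- function(blocks, within_intensity = 10, between_intensity = 2,
                     level_intensities = NULL, decay_exponent = NULL,
                     count_noise = c("none", "poisson"),
                     resolution = 25000, chrom = "chrS", seed = NULL,
                     min_block = 5) {
  count_noise <- match.arg(count_noise)
  tree <- normalize_blocks(blocks)
  validate_blocks(tree, min_block)
  if (within_intensity <= 0 || between_intensity <= 0)
    stop("intensities must be positive")
  if (within_intensity / between_intensity < 2)
    warning("within/between contrast below 2; blocks may be undetectable")
  structure(list(blocks = tree,
                 n_bins = sum(vapply(tree, function(b) b$width, numeric(1))),
                 within_intensity = within_intensity,
                 between_intensity = between_intensity,
                 level_intensities = level_intensities,
                 decay_exponent = decay_exponent,
                 count_noise = count_noise, resolution = resolution,
                 chrom = chrom, seed = seed, min_block = min_block),
            class = "SimSpec")
}

normalize_blocks <- function(blocks) {
  if (is.numeric(blocks))
    return(lapply(blocks, function(w) list(width = w, children = NULL)))
  lapply(blocks, function(b) {
    if (is.numeric(b)) b <- list(width = b, children = NULL)
    if (is.null(b$width)) stop("each block node needs a width")
    if (!is.null(b$children)) b$children <- normalize_blocks(b$children)
    b
  })
}

validate_blocks <- function(tree, min_block) {
  for (b in tree) {
    if (b$width < min_block)
      stop("block of width ", b$width, " is below the minimum of ",
           min_block)
    if (!is.null(b$children)) {
      tot <- sum(vapply(b$children, function(x) x$width, numeric(1)))
      if (tot != b$width)
        stop("children (", tot, " bins) do not tile their parent (",
             b$width, " bins)")
      validate_blocks(b$children, min_block)
    }
  }
}

# flatten the block tree: one row per block with level and bin span
block_table <- function(tree, offset = 0L, level = 1L) {
  rows <- list()
  pos <- offset
  for (b in tree) {
    rows[[length(rows) + 1L]] <-
      data.frame(start_bin = pos + 1L, end_bin = pos + b$width,
                 level = level)
    if (!is.null(b$children))
      rows[[length(rows) + 1L]] <-
        do.call(rbind, list(block_table(b$children, pos, level + 1L)))
    pos <- pos + b$width
  }
  do.call(rbind, rows)
}

#' Generate a synthetic contact matrix with known ground truth
#'
#' @param spec a [sim_spec()].
#' @return List with `cm` (a `ContactMatrix`) and `truth` (a `TADSet`
#'   listing every block at every level, depth 1 = top level).
#' @examples
#' sim <- simulate_matrix(sim_spec(c(10, 10), within_intensity = 10,
#'                                 between_intensity = 1))
#' sim$truth
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  blocks <- block_table(spec$blocks)
  n <- spec$n_bins
  depth <- matrix(0L, n, n)
  for (i in seq_len(nrow(blocks))) {
    rng <- blocks$start_bin[i]:blocks$end_bin[i]
    depth[rng, rng] <- depth[rng, rng] + 1L
  }
  intens <- if (!is.null(spec$level_intensities)) {
    if (max(depth) + 1 > length(spec$level_intensities))
      stop("level_intensities must cover shared depths 0..", max(depth))
    spec$level_intensities
  } else {
    ratio <- spec$within_intensity / spec$between_intensity
    spec$between_intensity * ratio^(0:max(depth))
  }
  mu <- matrix(intens[depth + 1L], n, n)
  if (!is.null(spec$decay_exponent)) {
    dist <- abs(outer(seq_len(n), seq_len(n), "-"))
    mu <- mu * (dist + 1)^(-spec$decay_exponent)
  }
  if (spec$count_noise == "poisson") {
    restore <- push_seed(spec$seed)
    on.exit(restore(), add = TRUE)
    ut <- which(upper.tri(mu, diag = TRUE))
    vals <- matrix(0, n, n)
    vals[ut] <- stats::rpois(length(ut), mu[ut])
    lo <- lower.tri(vals)
    vals[lo] <- t(vals)[lo]
  } else {
    vals <- mu
  }
  cm <- contact_matrix(vals, spec$resolution, spec$chrom)
  truth <- tad_set(chrom = rep(spec$chrom, nrow(blocks)),
                   start_bin = blocks$start_bin, end_bin = blocks$end_bin,
                   start_bp = bin_start_bp(cm, blocks$start_bin),
                   end_bp = bin_end_bp(cm, blocks$end_bin),
                   level = blocks$level)
  list(cm = cm, truth = truth)
}
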
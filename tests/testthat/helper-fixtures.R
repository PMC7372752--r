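# Shared fixtures, built in code at test time.

# plain block-constant matrix, independent of the simulate module
block_values <- function(widths, within = 10, between = 2) {
  n <- sum(widths)
  v <- matrix(between, n, n)
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  for (i in seq_along(widths))
    v[starts[i]:ends[i], starts[i]:ends[i]] <- within
  v
}

# three-level nested fixture: a 40-bin primary holding two 20-bin
# secondaries, the first of which holds two 10-bin tertiaries, next to a
# flat 30-bin primary. Sub-TAD enrichment is deliberately milder than the
# primary contrast (intensities 1 / 8 / 30 / 60 for shared depth 0-3), the
# regime in which each hierarchy level is resolved at its own scale.
nested_spec <- function(resolution = 25000) {
  blocks <- list(
    list(width = 40, children = list(
      list(width = 20,
           children = list(list(width = 10), list(width = 10))),
      list(width = 20))),
    list(width = 30))
  sim_spec(blocks, level_intensities = c(1, 8, 30, 60),
           resolution = resolution)
}

nested_truth_df <- function() {
  data.frame(start_bin = c(1, 41, 1, 21, 1, 11),
             end_bin = c(40, 70, 20, 40, 10, 20),
             level = c(1, 1, 2, 2, 3, 3))
}

# random flat block widths summing to at most max_bins
random_widths <- function(n_blocks, lo, hi, max_bins = Inf) {
  repeat {
    w <- sample(lo:hi, n_blocks, replace = TRUE)
    if (sum(w) <= max_bins) return(w)
  }
}
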
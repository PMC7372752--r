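#' Read a Hi-C contact matrix from a plain-text file
#'
#' Three text dialects are supported:
#' \describe{
#'   \item{`dense`}{an n x n whitespace- or tab-delimited matrix of counts,
#'     no row or column names. `bin_start` defaults to 0.}
#'   \item{`triplet`}{three columns `start_i start_j value`, one row per
#'     non-zero cell; coordinates are bin start positions on the resolution
#'     grid. Cells absent from the file are 0. Only one triangle needs to be
#'     listed; the matrix is mirrored across the diagonal.}
#'   \item{`bed3plus`}{n rows of `chrom start end` followed by the n matrix
#'     columns; the leading columns define bin order and `bin_start`.}
#' }
#'
#' Dense and bed3plus input must already be symmetric; asymmetric matrices
#' are rejected rather than silently symmetrized. Triplet input listing both
#' `(i, j)` and `(j, i)` must agree on the value.
#'
#' @param path file to read.
#' @param dialect one of `"dense"`, `"triplet"`, `"bed3plus"`.
#' @param resolution bin width in bp.
#' @param chrom chromosome name; for `bed3plus` it must match the file.
#' @param bin_start genomic coordinate of the first bin (dense and triplet
#'   dialects; ignored for bed3plus, which carries its own coordinates).
#' @return A [contact_matrix()] object.
#' @export
read_contact_matrix <- function(path,
                                dialect = c("dense", "triplet", "bed3plus"),
                                resolution, chrom = "chr1", bin_start = 0) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, header = FALSE)
  switch(dialect,
    dense = {
      vals <- as.matrix(dt)
      if (nrow(vals) != ncol(vals))
        stop("dense input is not square: ", nrow(vals), " x ", ncol(vals))
      contact_matrix(vals, resolution, chrom, bin_start)
    },
    triplet = {
      if (ncol(dt) != 3) stop("triplet input must have exactly 3 columns")
      pos_i <- dt[[1]]; pos_j <- dt[[2]]; val <- dt[[3]]
      if (any(val < 0)) stop("negative counts in triplet input")
      offs <- c(pos_i, pos_j) - bin_start
      if (any(offs %% resolution != 0))
        stop("triplet coordinate not on the resolution grid")
      i <- (pos_i - bin_start) %/% resolution + 1
      j <- (pos_j - bin_start) %/% resolution + 1
      if (any(i < 1) || any(j < 1))
        stop("triplet coordinate before bin_start")
      n <- max(i, j)
      vals <- matrix(0, n, n)
      vals[cbind(i, j)] <- val
      # mirror; where both triangles were listed they must agree
      tv <- t(vals)
      both <- vals != 0 & tv != 0
      if (any(vals[both] != tv[both]))
        stop("triplet input lists both (i,j) and (j,i) with different values")
      vals <- pmax(vals, tv)
      contact_matrix(vals, resolution, chrom, bin_start)
    },
    bed3plus = {
      if (ncol(dt) < 4) stop("bed3plus input needs chrom/start/end + matrix")
      n <- nrow(dt)
      if (ncol(dt) != n + 3)
        stop("bed3plus input is not n x (n+3): ", n, " rows, ",
             ncol(dt), " columns")
      chroms <- unique(as.character(dt[[1]]))
      if (length(chroms) != 1)
        stop("bed3plus input mixes chromosomes: ",
             paste(chroms, collapse = ", "))
      if (!missing(chrom) && !is.null(chrom) && chroms != chrom)
        stop("bed3plus chromosome ", chroms, " does not match ", chrom)
      starts <- as.numeric(dt[[2]])
      ord <- order(starts)
      if (any(diff(starts[ord]) != resolution))
        stop("bed3plus bins are not contiguous at the stated resolution")
      vals <- as.matrix(dt[, -(1:3)])[ord, ord, drop = FALSE]
      contact_matrix(vals, resolution, chroms, bin_start = starts[ord][1])
    })
}

#' Write a contact matrix in one of the text dialects
#'
#' Writing then re-reading any dialect reproduces integer counts exactly.
#' Triplet output lists the non-zero upper triangle (including diagonal).
#'
#' @param cm a `ContactMatrix`.
#' @param path output file.
#' @param dialect output format, as in [read_contact_matrix()].
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path,
                                 dialect = c("dense", "triplet",
                                             "bed3plus")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cm, "ContactMatrix"))
  n <- n_bins(cm)
  switch(dialect,
    dense = data.table::fwrite(as.data.frame(cm$values), path, sep = "\t",
                               col.names = FALSE),
    triplet = {
      ut <- which(upper.tri(cm$values, diag = TRUE) & cm$values != 0,
                  arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      dt <- data.table::data.table(
        start_i = bin_start_bp(cm, ut[, 1]),
        start_j = bin_start_bp(cm, ut[, 2]),
        value = cm$values[ut])
      data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    },
    bed3plus = {
      dt <- data.table::data.table(
        chrom = cm$chrom,
        start = bin_start_bp(cm, seq_len(n)),
        end = bin_end_bp(cm, seq_len(n)))
      dt <- cbind(dt, as.data.frame(cm$values))
      data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    })
  invisible(path)
}

#' Write called TADs to a BED file
#'
#' One row per TAD in 0-based half-open BED coordinates, sorted by start
#' then by hierarchy depth; the name column carries the depth label
#' (`Primary`, `Secondary`, `Tertiary`, then `Level4`, ...). A comment
#' header is always written, so an empty TAD set yields a header-only file.
#'
#' @param tads a `TADSet` (see [tad_set()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tads_bed <- function(tads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname", con)
  if (nrow(tads)) {
    ord <- order(tads$start_bp, tads$level, tads$end_bp)
    lines <- sprintf("%s\t%d\t%d\t%s",
                     tads$chrom[ord],
                     as.integer(tads$start_bp[ord]),
                     as.integer(tads$end_bp[ord]),
                     depth_label(tads$level[ord]))
    writeLines(lines, con)
  }
  invisible(path)
}

depth_label <- function(level) {
  lab <- c("Primary", "Secondary", "Tertiary")
  ifelse(level <= 3, lab[pmin(level, 3)], paste0("Level", level))
}

#' Read genomic intervals from a BED file
#'
#' Thin reader for annotation input (e.g., CTCF peaks): the first three
#' columns are used and returned as a `GRanges`. BED is 0-based half-open;
#' the returned ranges are 1-based closed, following Bioconductor
#' convention.
#'
#' @param path BED file; comment lines starting with `#` are skipped.
#' @return A `GenomicRanges::GRanges` object.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          fill = TRUE)
  if (ncol(dt) < 3) stop("BED input needs at least 3 columns")
  GenomicRanges::GRanges(
    seqnames = as.character(dt[[1]]),
    ranges = IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]))
}
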
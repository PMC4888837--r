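#' TSS-relative peak-density metaprofile
#'
#' Measures how peaks distribute around transcription start sites: for each
#' gene, peak intervals are mapped to TSS-relative, strand-oriented
#' coordinates (upstream negative, downstream positive), and each bin in
#' `[-window, window)` accumulates the number of (gene, peak) pairs whose
#' relative interval intersects it. The reported density is peaks per base
#' pair per gene: `count / (bin_width * n_genes)`.
#'
#' In `"interval"` mode a peak contributes to every bin it intersects; in
#' `"midpoint"` mode only to the bin containing its relative midpoint.
#'
#' @param peaks A `peak_set`.
#' @param genes A validated gene table (see [read_genes()]); must be
#'   non-empty.
#' @param window Half-window in bp each side of the TSS. Default 10000.
#' @param bin_width Bin width in bp; must divide `window`. Default 250.
#' @param mode `"interval"` (default) or `"midpoint"`.
#' @return An object of class `tss_profile`: a `data.frame` with columns
#'   `bin_start`, `bin_center`, `count`, `density`, and attributes
#'   `window`, `bin_width`, `n_genes`, `mode`.
#' @export
tss_profile <- function(peaks, genes, window = 10000L, bin_width = 250L,
                        mode = c("interval", "midpoint")) {
  mode <- match.arg(mode)
  .stop_if(nrow(genes) == 0L, "no genes supplied")
  stopifnot(window > 0, bin_width > 0, window %% bin_width == 0)
  n_bins <- as.integer(2L * window / bin_width)
  counts <- integer(n_bins)

  if (nrow(peaks)) {
    # genomic windows generously covering any peak that can touch the profile
    gw <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tss - window - 1L, 0L),
                     end = genes$tss + window + 2L)
    pairs <- .overlap_pairs(peaks, gw)
    for (k in seq_len(nrow(pairs))) {
      p <- pairs$i[k]; g <- pairs$j[k]
      tss <- genes$tss[g]
      if (genes$strand[g] == "+") {
        rs <- peaks$start[p] - tss
        re <- peaks$end[p] - tss
      } else {
        rs <- tss - peaks$end[p] + 1L
        re <- tss - peaks$start[p] + 1L
      }
      if (mode == "midpoint") {
        mid <- floor((rs + re - 1L) / 2)  # midpoint base of [rs, re)
        if (mid < -window || mid >= window) next
        b <- (mid + window) %/% bin_width + 1L
        counts[b] <- counts[b] + 1L
      } else {
        rs <- max(rs, -window)
        re <- min(re, window)
        if (rs >= re) next
        b1 <- (rs + window) %/% bin_width + 1L
        b2 <- (re - 1L + window) %/% bin_width + 1L
        counts[b1:b2] <- counts[b1:b2] + 1L
      }
    }
  }
  bin_start <- seq(-window, window - bin_width, by = bin_width)
  structure(
    data.frame(bin_start = as.integer(bin_start),
               bin_center = bin_start + bin_width / 2,
               count = counts,
               density = counts / (bin_width * nrow(genes))),
    window = as.integer(window), bin_width = as.integer(bin_width),
    n_genes = nrow(genes), mode = mode,
    class = c("tss_profile", "data.frame"))
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf(
    "TSS metaprofile: +/-%d bp in %d bins of %d bp over %d gene(s) [%s mode]\n",
    attr(x, "window"), nrow(x), attr(x, "bin_width"), attr(x, "n_genes"),
    attr(x, "mode")))
  cat(sprintf("  peak density: max %.3g at %+d bp, total (gene,peak,bin) hits %d\n",
              max(x$density), as.integer(x$bin_center[which.max(x$density)]),
              sum(x$count)))
  invisible(x)
}

#' @export
plot.tss_profile <- function(x, ..., col = "steelblue") {
  graphics::plot(x$bin_center, x$density, type = "l", col = col,
                 xlab = "position relative to TSS (bp)",
                 ylab = "peaks per bp per gene", ...)
  graphics::abline(v = 0, lty = 2, col = "grey60")
  invisible(x)
}

#' Write a TSS profile as TSV
#'
#' @param profile A [tss_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bin_center_bp\tdensity", con)
  writeLines(sprintf("%g\t%.8g", profile$bin_center, profile$density), con)
  invisible(path)
}
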
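#' Promoter window parameters
#'
#' A promoter is a fixed strand-aware window around the TSS: `upstream` bp
#' before it and `downstream` bp after it (in transcription direction).
#'
#' @param upstream Upstream extent in bp. Default 1000.
#' @param downstream Downstream extent in bp. Default 100.
#' @return A list of class `promoter_params`.
#' @export
promoter_params <- function(upstream = 1000L, downstream = 100L) {
  stopifnot(upstream >= 0, downstream >= 0)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream)),
            class = "promoter_params")
}

# Strand-aware promoter windows, 0-based half-open, clamped at 0.
promoter_windows <- function(genes, params = promoter_params()) {
  up <- params$upstream
  down <- params$downstream
  start <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  end <- ifelse(genes$strand == "+", genes$tss + down + 1L, genes$tss + up + 1L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(as.integer(start), 0L), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# Overlap pairs between two 0-based half-open interval tables, per chrom.
# Returns a data.frame of (i, j) row indices.
.overlap_pairs <- function(x, y) {
  pieces <- lapply(intersect(unique(x$chrom), unique(y$chrom)), function(chrom) {
    xi <- which(x$chrom == chrom)
    yi <- which(y$chrom == chrom)
    hits <- IRanges::findOverlaps(.as_iranges(x$start[xi], x$end[xi]),
                                  .as_iranges(y$start[yi], y$end[yi]))
    data.frame(i = xi[S4Vectors::queryHits(hits)],
               j = yi[S4Vectors::subjectHits(hits)])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(i = integer(0), j = integer(0))
  out
}

#' Overlap two peak sets into merged clusters
#'
#' Two peaks overlap iff their half-open intervals intersect by at least 1
#' bp (touching boundaries do not overlap). Connected components of the
#' overlap graph across both sets are merged clusters; a cluster containing
#' members of both sets is shared, otherwise it counts to the side it came
#' from. This reproduces mergePeaks-style Venn counting, where the counting
#' unit is the merged cluster, not the raw peak; raw-peak tallies are also
#' reported.
#'
#' @param a,b `peak_set` objects (sorted, internally non-overlapping).
#' @return An object of class `overlap_result`: list with `n_a_only`,
#'   `n_shared`, `n_b_only`, `shared_intervals` (merged intervals of shared
#'   clusters), `clusters` (all merged clusters with per-set member
#'   counts), `raw` (raw-peak accounting) and `labels`.
#' @export
overlap_peaksets <- function(a, b) {
  both <- rbind(data.frame(chrom = a$chrom, start = a$start, end = a$end,
                           set = "a", stringsAsFactors = FALSE),
                data.frame(chrom = b$chrom, start = b$start, end = b$end,
                           set = "b", stringsAsFactors = FALSE))
  if (nrow(both) == 0L) {
    clusters <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), n_a = integer(0),
                           n_b = integer(0))
  } else {
    pieces <- lapply(unique(both$chrom), function(chrom) {
      i <- which(both$chrom == chrom)
      ir <- .as_iranges(both$start[i], both$end[i])
      # min.gapwidth = 0: merge only genuine >= 1 bp intersections,
      # never merely adjacent intervals
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      hits <- IRanges::findOverlaps(red, ir)
      member_set <- both$set[i][S4Vectors::subjectHits(hits)]
      q <- S4Vectors::queryHits(hits)
      coords <- .from_iranges(red)
      data.frame(chrom = chrom, start = coords$start, end = coords$end,
                 n_a = as.integer(tabulate(q[member_set == "a"], length(red))),
                 n_b = as.integer(tabulate(q[member_set == "b"], length(red))),
                 stringsAsFactors = FALSE)
    })
    clusters <- do.call(rbind, pieces)
    clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
    rownames(clusters) <- NULL
  }
  shared <- clusters$n_a > 0L & clusters$n_b > 0L
  structure(list(
    n_a_only = sum(clusters$n_a > 0L & clusters$n_b == 0L),
    n_shared = sum(shared),
    n_b_only = sum(clusters$n_b > 0L & clusters$n_a == 0L),
    shared_intervals = clusters[shared, c("chrom", "start", "end"),
                                drop = FALSE],
    clusters = clusters,
    raw = list(a_total = nrow(a), b_total = nrow(b),
               a_in_shared = sum(clusters$n_a[shared]),
               b_in_shared = sum(clusters$n_b[shared])),
    labels = c(a = attr(a, "label") %||% "A", b = attr(b, "label") %||% "B")
  ), class = "overlap_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Peak-set overlap (%s vs %s), merged-cluster counts:\n",
              x$labels[["a"]], x$labels[["b"]]))
  cat(sprintf("  %s only: %d\n  shared: %d\n  %s only: %d\n",
              x$labels[["a"]], x$n_a_only, x$n_shared,
              x$labels[["b"]], x$n_b_only))
  cat(sprintf("  raw peaks in shared clusters: %d (%s), %d (%s)\n",
              x$raw$a_in_shared, x$labels[["a"]],
              x$raw$b_in_shared, x$labels[["b"]]))
  invisible(x)
}

#' Assign peaks to promoters
#'
#' A peak is assigned to every gene whose strand-aware promoter window
#' (`[tss - upstream, tss + downstream]` in transcription direction) it
#' intersects by at least 1 bp.
#'
#' @param peaks A `peak_set`.
#' @param genes A validated gene table (see [read_genes()]).
#' @param params A [promoter_params()].
#' @return A `data.frame` with one row per (peak, gene) assignment:
#'   `peak` (row index into `peaks`), `chrom`, `start`, `end`, `gene_id`.
#' @export
assign_promoters <- function(peaks, genes, params = promoter_params()) {
  win <- promoter_windows(genes, params)
  pairs <- .overlap_pairs(peaks, win)
  out <- data.frame(peak = pairs$i,
                    chrom = peaks$chrom[pairs$i],
                    start = peaks$start[pairs$i],
                    end = peaks$end[pairs$i],
                    gene_id = win$gene_id[pairs$j],
                    stringsAsFactors = FALSE)
  out[order(out$peak, out$gene_id), , drop = FALSE]
}

#' Count shared clusters at promoters
#'
#' Number of shared (cobound) clusters from [overlap_peaksets()] whose
#' merged interval intersects at least one promoter window. The number of
#' distinct genes with a cobound promoter is attached as attribute
#' `n_genes`.
#'
#' @param overlap An `overlap_result`.
#' @param genes A validated gene table.
#' @param params A [promoter_params()].
#' @return Integer count of cobound promoter clusters (attribute `n_genes`:
#'   distinct genes involved).
#' @export
cobound_promoter_count <- function(overlap, genes,
                                   params = promoter_params()) {
  stopifnot(inherits(overlap, "overlap_result"))
  shared <- overlap$shared_intervals
  if (nrow(shared) == 0L) {
    return(structure(0L, n_genes = 0L))
  }
  win <- promoter_windows(genes, params)
  pairs <- .overlap_pairs(shared, win)
  structure(length(unique(pairs$i)),
            n_genes = length(unique(win$gene_id[pairs$j])))
}

#' Fractional overlap of shared clusters with a third peak set
#'
#' Percentage of base clusters intersecting at least one peak of `other`,
#' rounded to the nearest integer percent, reported alongside the raw
#' counts.
#'
#' @param base Shared clusters: an `overlap_result`, or a `data.frame` of
#'   intervals (`chrom`, `start`, `end`). Must be non-empty.
#' @param other A `peak_set` (or interval `data.frame`).
#' @return A list of class `fraction_overlap` with `percent` (nearest
#'   integer), `fraction`, `n_base`, `n_hit`.
#' @export
fraction_overlap <- function(base, other) {
  if (inherits(base, "overlap_result")) base <- base$shared_intervals
  .stop_if(nrow(base) == 0L, "empty base cluster set")
  pairs <- .overlap_pairs(base, other)
  n_hit <- length(unique(pairs$i))
  structure(list(percent = .round_half_up(100 * n_hit / nrow(base)),
                 fraction = n_hit / nrow(base),
                 n_base = nrow(base), n_hit = n_hit),
            class = "fraction_overlap")
}

#' @export
print.fraction_overlap <- function(x, ...) {
  cat(sprintf("%d of %d clusters (%d%%) overlap the comparison set\n",
              x$n_hit, x$n_base, as.integer(x$percent)))
  invisible(x)
}
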
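#' Peak-calling parameters
#'
#' Variable-width DamID peaks are maximal gap-limited runs of enriched GATC
#' cut sites, filtered by two deterministic thresholds: at least
#' `min_norm_reads` normalized reads per peak (per 10 million reads
#' sequenced) and at least `min_fold` more normalized reads than the Dam-GFP
#' control.
#'
#' @param max_gap Maximum distance in bp between consecutive member cut
#'   sites joined into one candidate region. Default 1500 (about six times
#'   the ~256 bp expected GATC spacing).
#' @param min_norm_reads Minimum normalized reads per peak. Default 50.
#' @param min_fold Minimum fold over control. Default 2.
#' @param pseudocount Additive pseudocount (normalized reads) applied to
#'   both numerator and denominator of the fold ratio, guarding
#'   control-empty regions. Default 1.
#' @param pad Symmetric padding in bp added to each candidate region's
#'   boundaries. Default 0 (regions span exactly their member cut sites).
#' @param min_sites Minimum number of member cut sites per emitted peak.
#'   Default 3: a peak must be supported by at least two GATC fragments,
#'   which suppresses single-site sampling noise that the normalized-read
#'   floor alone cannot exclude in deeply covered genomes.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(max_gap = 1500L, min_norm_reads = 50,
                        min_fold = 2, pseudocount = 1, pad = 0L,
                        min_sites = 3L) {
  stopifnot(max_gap > 0, min_norm_reads > 0, min_fold > 0, pseudocount > 0,
            pad >= 0, min_sites >= 1)
  structure(list(max_gap = as.integer(max_gap),
                 min_norm_reads = min_norm_reads, min_fold = min_fold,
                 pseudocount = pseudocount, pad = as.integer(pad),
                 min_sites = as.integer(min_sites)),
            class = "peak_params")
}

# Control value at given sample sites on one chromosome (0 where absent).
.control_at <- function(control, chrom, sites) {
  if (is.null(control)) return(rep(0, length(sites)))
  i <- which(control$chrom == chrom)
  v <- rep(0, length(sites))
  m <- match(sites, control$pos[i])
  hit <- !is.na(m)
  v[hit] <- control$value[i][m[hit]]
  v
}

#' Candidate enriched regions from a normalized track
#'
#' Member cut sites are covered sites (`value > 0`); when a control track is
#' supplied, a member site must additionally be site-level enriched:
#' `(value + pseudocount) / (c + pseudocount) >= min_fold`, where `c` is the
#' control value at the site floored at the control's genome-wide mean per
#' covered site (the expected background density).
#' Maximal runs of member sites with consecutive sites at most `max_gap` bp
#' apart form one candidate region spanning its outermost member sites
#' (plus `pad`). Candidates on different chromosomes never merge.
#'
#' The site-level enrichment test matters in deeply sequenced libraries
#' where every cut site carries background reads: without it, covered-site
#' runs coalesce into chromosome-wide candidates in which planted signal is
#' diluted below any fold threshold.
#'
#' @param sample A [normalize_counts()] track.
#' @param params A [peak_params()].
#' @param control Optional control `normalized_track` (its own
#'   normalization).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `n_sites`
#'   and a list-column `sites` of member cut-site positions.
#' @export
candidate_regions <- function(sample, params = peak_params(), control = NULL) {
  stopifnot(inherits(sample, "normalized_track"), inherits(params, "peak_params"))
  pieces <- lapply(unique(sample$chrom), function(chrom) {
    i <- which(sample$chrom == chrom)
    pos <- sample$pos[i]
    val <- sample$value[i]
    o <- order(pos)
    pos <- pos[o]; val <- val[o]
    member <- val > 0
    if (!is.null(control) && nrow(control) > 0L) {
      # floor the control at its genome-wide mean per covered site: a site
      # must beat both the local control and the expected background
      # density, otherwise sites with an accidentally empty control qualify
      # on sampling noise alone
      cv <- pmax(.control_at(control, chrom, pos), mean(control$value))
      member <- member &
        (val + params$pseudocount) / (cv + params$pseudocount) >= params$min_fold
    }
    pos <- pos[member]
    if (length(pos) == 0L) return(NULL)
    new_run <- c(TRUE, diff(pos) > params$max_gap)
    run <- cumsum(new_run)
    first <- pos[!duplicated(run)]
    last <- pos[!duplicated(run, fromLast = TRUE)]
    data.frame(chrom = chrom,
               start = pmax(first - params$pad, 0L),
               end = last + 1L + params$pad,
               n_sites = as.integer(table(run)),
               sites = I(unname(split(pos, run))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      sites = I(list()))
  }
  rownames(out) <- NULL
  out
}

#' Score candidate regions and apply the peak filters
#'
#' For each candidate, `norm_reads` is the sum of sample normalized counts
#' over its member cut sites and `control_norm_reads` the sum of control
#' normalized counts over all cut sites inside `[start, end)`. The fold
#' ratio is `(norm_reads + pseudocount) / (control_norm_reads +
#' pseudocount)`. A candidate is emitted iff `norm_reads >= min_norm_reads`,
#' `fold >= min_fold` and `n_sites >= min_sites`.
#'
#' @param candidates Output of [candidate_regions()].
#' @param sample The sample `normalized_track`.
#' @param control The control `normalized_track` (normalized on its own
#'   retained total), or `NULL`/empty: regions then score against a zero
#'   control, with a warning.
#' @param params A [peak_params()].
#' @param label Factor name attached to the peak set.
#' @return An object of class `peak_set`: a sorted `data.frame` of
#'   non-overlapping peaks with columns `chrom`, `start`, `end`, `n_sites`,
#'   `norm_reads`, `control_norm_reads`, `fold`, and attribute `label`.
#' @export
score_and_filter <- function(candidates, sample, control = NULL,
                             params = peak_params(), label = "sample") {
  stopifnot(inherits(params, "peak_params"))
  if (is.null(control) || nrow(control) == 0L) {
    warning("empty control track: scoring regions against zero control")
    control <- NULL
  }
  n <- nrow(candidates)
  norm_reads <- numeric(n)
  ctrl_reads <- numeric(n)
  if (n > 0L) {
    sval <- stats::setNames(sample$value, paste(sample$chrom, sample$pos))
    for (k in seq_len(n)) {
      sites <- candidates$sites[[k]]
      norm_reads[k] <- sum(sval[paste(candidates$chrom[k], sites)])
      if (!is.null(control)) {
        i <- which(control$chrom == candidates$chrom[k] &
                     control$pos >= candidates$start[k] &
                     control$pos < candidates$end[k])
        ctrl_reads[k] <- sum(control$value[i])
      }
    }
  }
  fold <- (norm_reads + params$pseudocount) / (ctrl_reads + params$pseudocount)
  keep <- norm_reads >= params$min_norm_reads & fold >= params$min_fold &
    candidates$n_sites >= params$min_sites
  out <- data.frame(chrom = candidates$chrom[keep],
                    start = candidates$start[keep],
                    end = candidates$end[keep],
                    n_sites = candidates$n_sites[keep],
                    norm_reads = norm_reads[keep],
                    control_norm_reads = ctrl_reads[keep],
                    fold = fold[keep], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = label, params = params,
            class = c("peak_set", "data.frame"))
}

#' Call DamID peaks from sample and control libraries
#'
#' End-to-end composition of the DamID signal and peak stages: reads are
#' filtered to GATC-anchored unique alignments (duplicates retained),
#' counted per cut site, normalized to reads per ten million, grouped into
#' variable-width candidate regions, and filtered against the identically
#' processed Dam-GFP control.
#'
#' @param sample,control A SAM/BAM file path or a read `data.frame` (see
#'   [read_sam_reads()]). The control is the Dam-GFP background library.
#' @param index A [gatc_index()].
#' @param filter A [filter_params()].
#' @param params A [peak_params()].
#' @param label Factor name for the resulting peak set.
#' @param verbose Log stage accounting. Default `FALSE`.
#' @return A `peak_set` (see [score_and_filter()]).
#' @export
call_damid_peaks <- function(sample, control, index,
                             filter = filter_params(),
                             params = peak_params(), label = "sample",
                             verbose = FALSE) {
  tracks <- lapply(list(sample = sample, control = control), function(x) {
    reads <- if (is.character(x)) read_sam_reads(x, verbose = verbose) else x
    normalize_counts(count_sites(filter_reads(reads, index, filter,
                                              verbose = verbose), index))
  })
  cand <- candidate_regions(tracks$sample, params, control = tracks$control)
  score_and_filter(cand, tracks$sample, tracks$control, params, label = label)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("DamID peak set '%s': %d peak(s)\n", attr(x, "label"), nrow(x)))
  if (nrow(x)) {
    w <- x$end - x$start
    cat(sprintf("  width: median %d bp [%d-%d]; norm_reads: median %.1f; fold: median %.2f\n",
                as.integer(stats::median(w)), min(w), max(w),
                stats::median(x$norm_reads), stats::median(x$fold)))
  }
  invisible(x)
}

#' @export
summary.peak_set <- function(object, ...) {
  out <- list(label = attr(object, "label"), n_peaks = nrow(object),
              total_width = sum(object$end - object$start),
              mean_norm_reads = if (nrow(object)) mean(object$norm_reads) else NA_real_,
              mean_fold = if (nrow(object)) mean(object$fold) else NA_real_)
  class(out) <- "summary.peak_set"
  out
}

#' @export
print.summary.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s': %d peaks, %d bp total, mean norm_reads %.1f, mean fold %.2f\n",
              x$label, x$n_peaks, x$total_width, x$mean_norm_reads, x$mean_fold))
  invisible(x)
}

#' Write / read a peak set
#'
#' Writes `<prefix>.bed` (BED6; name is `label_rank`, score the rounded
#' normalized read count) and `<prefix>.tsv` (all peak columns, with the
#' label recorded in a comment header). `read_peaks` restores a `peak_set`
#' from the TSV.
#'
#' @param peaks A `peak_set`.
#' @param prefix Output path prefix.
#' @param path Path to a `<prefix>.tsv` file.
#' @return `write_peaks` returns the two paths invisibly; `read_peaks`
#'   returns a `peak_set`.
#' @export
write_peaks <- function(peaks, prefix) {
  stopifnot(inherits(peaks, "peak_set"))
  label <- attr(peaks, "label")
  bed <- sprintf("%s.bed", prefix)
  tsv <- sprintf("%s.tsv", prefix)
  bed_lines <- if (nrow(peaks)) {
    sprintf("%s\t%d\t%d\t%s_%d\t%d\t.", peaks$chrom, peaks$start, peaks$end,
            label, seq_len(nrow(peaks)),
            as.integer(.round_half_up(peaks$norm_reads)))
  } else character(0)
  writeLines(bed_lines, bed)
  con <- file(tsv, "w")
  writeLines(sprintf("# label=%s", label), con)
  writeLines("chrom\tstart\tend\tn_sites\tnorm_reads\tcontrol_norm_reads\tfold", con)
  if (nrow(peaks)) {
    writeLines(sprintf("%s\t%d\t%d\t%d\t%.10g\t%.10g\t%.10g", peaks$chrom,
                       peaks$start, peaks$end, peaks$n_sites,
                       peaks$norm_reads, peaks$control_norm_reads,
                       peaks$fold), con)
  }
  close(con)
  invisible(c(bed = bed, tsv = tsv))
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  label <- sub("^# label=", "", grep("^# label=", lines, value = TRUE))
  if (length(label) != 1L) label <- "peaks"
  body <- lines[!grepl("^#", lines)]
  .stop_if(length(body) < 1L, "malformed peaks TSV: no header")
  body <- body[-1L]
  if (length(body) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      norm_reads = numeric(0), control_norm_reads = numeric(0),
                      fold = numeric(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    out <- data.frame(
      chrom = vapply(parts, `[[`, "", 1L),
      start = as.integer(vapply(parts, `[[`, "", 2L)),
      end = as.integer(vapply(parts, `[[`, "", 3L)),
      n_sites = as.integer(vapply(parts, `[[`, "", 4L)),
      norm_reads = as.numeric(vapply(parts, `[[`, "", 5L)),
      control_norm_reads = as.numeric(vapply(parts, `[[`, "", 6L)),
      fold = as.numeric(vapply(parts, `[[`, "", 7L)),
      stringsAsFactors = FALSE)
  }
  structure(out, label = label, class = c("peak_set", "data.frame"))
}

#' Construct a peak set from plain intervals
#'
#' Convenience constructor used when peak intervals originate outside the
#' caller (e.g. published counts or external BED files).
#'
#' @param chrom,start,end Vectors defining 0-based half-open intervals.
#' @param label Factor name.
#' @return A `peak_set` with unscored peaks (`norm_reads` etc. `NA`).
#' @export
peak_set <- function(chrom, start, end, label = "peaks") {
  stopifnot(length(start) == length(end), all(start < end))
  chrom <- rep(as.character(chrom), length.out = length(start))
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end),
                    n_sites = rep(NA_integer_, length(start)),
                    norm_reads = rep(NA_real_, length(start)),
                    control_norm_reads = rep(NA_real_, length(start)),
                    fold = rep(NA_real_, length(start)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = label, class = c("peak_set", "data.frame"))
}
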
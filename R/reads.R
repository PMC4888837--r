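#' Read filtering parameters
#'
#' @param mapq_min Reads must have mapping quality strictly greater than
#'   this to count as uniquely aligned. Default 10.
#' @param anchor_tolerance Maximum distance in bp between a read's
#'   five-prime end and the nearest GATC cut site. Default 0 (exact
#'   anchoring).
#' @param keep_duplicates Keep reads flagged as duplicates. Default `TRUE`:
#'   in DamID most reads align to a limited number of GATC sites, so
#'   duplicates are genuine signal, reversing the ChIP-seq convention.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(mapq_min = 10L, anchor_tolerance = 0L,
                          keep_duplicates = TRUE) {
  stopifnot(anchor_tolerance >= 0, mapq_min >= 0)
  structure(list(mapq_min = as.integer(mapq_min),
                 anchor_tolerance = as.integer(anchor_tolerance),
                 keep_duplicates = isTRUE(keep_duplicates)),
            class = "filter_params")
}

#' Load aligned reads from a SAM file
#'
#' Ingests the minimal alignment fields the DamID pipeline uses: reference
#' name, position, strand, MAPQ, duplicate flag, and the CIGAR-derived
#' reference span. Unmapped, secondary and supplementary records are
#' dropped (counted in the message when `verbose`).
#'
#' @param path Path to a headered SAM (or BAM) file.
#' @param verbose Log record accounting. Default `FALSE`.
#' @return A `data.frame` of reads with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `mapq`, `is_duplicate`, carrying an
#'   `input_total` attribute (records before any filtering).
#' @export
read_sam_reads <- function(path, verbose = FALSE) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "mapq", "cigar", "strand")))[[1L]]

  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  drop <- unmapped | secondary | supplementary
  .msg(verbose, sprintf(
    "read_sam_reads: %d records (%d unmapped, %d secondary, %d supplementary dropped)",
    length(flag), sum(unmapped), sum(secondary), sum(supplementary)))

  keep <- !drop
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  reads <- data.frame(
    chrom = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + span,
    strand = as.character(res$strand[keep]),
    mapq = res$mapq[keep],
    is_duplicate = bitwAnd(flag[keep], 1024L) != 0L,
    stringsAsFactors = FALSE
  )
  attr(reads, "input_total") <- length(flag)
  reads
}

#' Write aligned reads as a minimal SAM file
#'
#' Emits a headered single-end SAM with the fields the pipeline consumes;
#' sequence and quality are omitted (`*`). Used by the simulator and for
#' round-trip testing.
#'
#' @param reads A read `data.frame` (see [read_sam_reads()]).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(reads)) {
    dup <- if (is.null(reads$is_duplicate)) rep(FALSE, nrow(reads)) else reads$is_duplicate
    flag <- ifelse(reads$strand == "-", 16L, 0L) + ifelse(dup, 1024L, 0L)
    writeLines(sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(reads)), flag, reads$chrom,
                       reads$start + 1L, reads$mapq,
                       reads$end - reads$start), con)
  }
  invisible(path)
}

# Strand-aware five-prime position of each read.
.five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

# Nearest cut site (leftmost on ties) for positions on one chromosome.
# Returns list(site, dist); site is NA when the chromosome has no cut sites.
.nearest_site <- function(pos, sites) {
  if (length(sites) == 0L) {
    return(list(site = rep(NA_integer_, length(pos)),
                dist = rep(Inf, length(pos))))
  }
  j <- findInterval(pos, sites)
  left <- ifelse(j >= 1L, sites[pmax(j, 1L)], NA_integer_)
  right <- ifelse(j < length(sites), sites[pmin(j + 1L, length(sites))], NA_integer_)
  dl <- ifelse(is.na(left), Inf, pos - left)
  dr <- ifelse(is.na(right), Inf, right - pos)
  # leftmost wins ties
  use_left <- dl <= dr
  list(site = as.integer(ifelse(use_left, left, right)),
       dist = pmin(dl, dr))
}

#' Filter reads to GATC-anchored unique alignments
#'
#' A read is retained iff its mapping quality is strictly greater than
#' `mapq_min` and its strand-aware five-prime end (alignment start on `+`,
#' last aligned base on `-`) lies within `anchor_tolerance` bp of a GATC
#' cut site on its chromosome. Reads anchored away from GATC sites are much
#' more likely to be nonspecific noise. Duplicates are retained by default.
#' Input order is preserved.
#'
#' @param reads Read `data.frame` (see [read_sam_reads()]).
#' @param index A [gatc_index()] covering every chromosome in `reads`.
#' @param params A [filter_params()].
#' @param verbose Log accounting. Default `FALSE`.
#' @return The retained subset of `reads`, with attribute `input_total`.
#' @export
filter_reads <- function(reads, index, params = filter_params(),
                         verbose = FALSE) {
  stopifnot(inherits(index, "gatc_index"), inherits(params, "filter_params"))
  input_total <- attr(reads, "input_total")
  if (is.null(input_total)) input_total <- nrow(reads)

  missing_chrom <- setdiff(unique(reads$chrom), names(index$motif_starts))
  .stop_if(length(missing_chrom) > 0L,
           sprintf("chromosome '%s' absent from GATC index", missing_chrom[1L]))

  keep <- rep(FALSE, nrow(reads))
  if (nrow(reads)) {
    fp <- .five_prime(reads)
    for (chrom in unique(reads$chrom)) {
      i <- which(reads$chrom == chrom)
      ns <- .nearest_site(fp[i], cut_sites(index, chrom))
      keep[i] <- ns$dist <= params$anchor_tolerance
    }
    keep <- keep & reads$mapq > params$mapq_min
    if (!params$keep_duplicates) keep <- keep & !reads$is_duplicate
  }
  .msg(verbose, sprintf(
    "filter_reads: %d/%d retained (mapq_min=%d, tolerance=%d, dups %s)",
    sum(keep), nrow(reads), params$mapq_min, params$anchor_tolerance,
    if (params$keep_duplicates) "kept" else "dropped"))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "input_total") <- input_total
  out
}

#' Count retained reads per GATC cut site
#'
#' Each retained read is assigned to the cut site nearest its five-prime end
#' (leftmost site on equidistant ties). The sum of counts equals the number
#' of retained reads.
#'
#' @param retained Reads that passed [filter_reads()] with the same index.
#' @param index The [gatc_index()] used for filtering.
#' @return An object of class `fragment_counts`: a `data.frame` with columns
#'   `chrom`, `cut_site`, `count`, sorted by chromosome then position, with
#'   attributes `retained_total` and `input_total`.
#' @export
count_sites <- function(retained, index) {
  stopifnot(inherits(index, "gatc_index"))
  input_total <- attr(retained, "input_total")
  if (is.null(input_total)) input_total <- nrow(retained)

  if (nrow(retained) == 0L) {
    out <- data.frame(chrom = character(0), cut_site = integer(0),
                      count = integer(0))
  } else {
    fp <- .five_prime(retained)
    pieces <- lapply(sort(unique(retained$chrom)), function(chrom) {
      i <- which(retained$chrom == chrom)
      site <- .nearest_site(fp[i], cut_sites(index, chrom))$site
      tab <- table(site)
      data.frame(chrom = chrom, cut_site = as.integer(names(tab)),
                 count = as.integer(tab), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$chrom, out$cut_site), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, retained_total = nrow(retained), input_total = input_total,
            class = c("fragment_counts", "data.frame"))
}

#' Normalize per-site counts to reads per ten million
#'
#' Scales raw per-cut-site counts by `1e7 / retained_total`, the unit in
#' which the peak-calling thresholds are stated ("normalized reads per 10
#' million reads sequenced"). The normalized values always sum to 1e7.
#'
#' @param counts A [count_sites()] result.
#' @return An object of class `normalized_track`: a `data.frame` with
#'   columns `chrom`, `pos`, `value`, and attributes `norm_factor` and
#'   `retained_total`.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "fragment_counts"))
  retained_total <- attr(counts, "retained_total")
  .stop_if(retained_total == 0L, "empty library")
  norm_factor <- 1e7 / retained_total
  structure(
    data.frame(chrom = counts$chrom, pos = counts$cut_site,
               value = counts$count * norm_factor, stringsAsFactors = FALSE),
    norm_factor = norm_factor, retained_total = retained_total,
    class = c("normalized_track", "data.frame"))
}

#' @export
print.normalized_track <- function(x, ...) {
  cat(sprintf(
    "Normalized DamID track: %d covered cut site(s), retained_total=%d, norm_factor=%.4g\n",
    nrow(x), attr(x, "retained_total"), attr(x, "norm_factor")))
  invisible(x)
}

#' Build a normalized, read-extended coverage track
#'
#' Each read is extended by `extension` bp both upstream and downstream
#' (reflecting the size of DamID-enriched regions), clamped to the
#' chromosome, piled up, and the per-base coverage scaled by
#' `1e7 / n_reads`. Zero-coverage runs are omitted.
#'
#' @param reads Retained read `data.frame`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param extension Extension in bp each side. Default 1000.
#' @return A `data.frame` of non-overlapping sorted bedGraph records
#'   (`chrom`, `start`, `end`, `value`), 0-based half-open.
#' @export
make_bedgraph <- function(reads, chrom_lengths, extension = 1000L) {
  stopifnot(extension >= 0)
  if (nrow(reads) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  norm_factor <- 1e7 / nrow(reads)
  pieces <- lapply(intersect(names(chrom_lengths), unique(reads$chrom)),
                   function(chrom) {
    i <- which(reads$chrom == chrom)
    len <- as.integer(chrom_lengths[[chrom]])
    s <- pmax(reads$start[i] - extension, 0L)
    e <- pmin(reads$end[i] + extension, len)
    cov <- IRanges::coverage(.as_iranges(s, e), width = len)
    rs <- cumsum(c(0L, S4Vectors::runLength(cov)))
    v <- S4Vectors::runValue(cov)
    nz <- which(v > 0)
    if (length(nz) == 0L) return(NULL)
    data.frame(chrom = chrom, start = rs[nz], end = rs[nz + 1L],
               value = v[nz] * norm_factor, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write / read bedGraph records
#'
#' UCSC bedGraph dialect: tab-separated `chrom start end value`, values with
#' 4 decimal places, optional `track` line.
#'
#' @param bg bedGraph `data.frame` from [make_bedgraph()].
#' @param path File path.
#' @param track_line Emit a `track type=bedGraph` header line. Default
#'   `FALSE`.
#' @param name Track name used when `track_line` is `TRUE`.
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph`
#'   returns the records `data.frame`.
#' @export
write_bedgraph <- function(bg, path, track_line = FALSE, name = "damid") {
  con <- file(path, "w")
  on.exit(close(con))
  if (track_line) {
    writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  }
  if (nrow(bg)) {
    writeLines(sprintf("%s\t%d\t%d\t%.4f", bg$chrom, bg$start, bg$end,
                       bg$value), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track\\b|#|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             start = as.integer(vapply(parts, `[[`, "", 2L)),
             end = as.integer(vapply(parts, `[[`, "", 3L)),
             value = as.numeric(vapply(parts, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}
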
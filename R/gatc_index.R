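#' Build a GATC cut-site index for a genome
#'
#' DamID relies on Dam methylase marking adenines within GATC motifs, and
#' sequencing libraries are built from fragments released at those motifs.
#' Every downstream filtering and counting step in this package is anchored
#' on the positions of the GATC motif: this function scans a genome and
#' records, per chromosome, the 0-based start position of every exact
#' occurrence of `GATC`.
#'
#' The modeled fragment boundary (the "cut site") is `motif_start +
#' cut_offset`. The default offset of 2 places the boundary inside the motif
#' at GA^TC, the DpnI-relevant position where DamID fragments begin; reads
#' are expected to start just downstream of it.
#'
#' Matching is case-insensitive and exact: windows containing `N` (or any
#' ambiguity) never match. GATC is its own reverse complement, so the index
#' is strand-symmetric by construction.
#'
#' @param genome A genome as a named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file (multi-record,
#'   wrapped lines allowed).
#' @param cut_offset Integer offset in bp from motif start to the modeled
#'   fragment boundary. Default 2.
#' @return An object of class `gatc_index`: a list with `chrom_lengths`
#'   (named integer), `motif_starts` (named list of strictly increasing
#'   0-based integer vectors) and `cut_offset`.
#' @examples
#' idx <- gatc_index(c(c1 = "AAGATCAA"))
#' idx$motif_starts$c1   # 2
#' cut_sites(idx, "c1")  # 4
#' @export
gatc_index <- function(genome, cut_offset = 2L) {
  stopifnot(length(cut_offset) == 1L, !is.na(cut_offset), cut_offset >= 0)
  cut_offset <- as.integer(cut_offset)

  seqs <- .load_genome(genome)
  .stop_if(length(seqs) == 0L, "empty genome: no sequences found")

  motif_starts <- lapply(seq_along(seqs), function(i) {
    m <- Biostrings::matchPattern("GATC", seqs[[i]], fixed = TRUE)
    as.integer(IRanges::start(m) - 1L)
  })
  names(motif_starts) <- names(seqs)

  structure(
    list(
      chrom_lengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
      motif_starts = motif_starts,
      cut_offset = cut_offset
    ),
    class = "gatc_index"
  )
}

# Accepts DNAStringSet, named character vector, or FASTA path.
# Validates the alphabet: only A/C/G/T/N (case-insensitive) are allowed;
# the first offending position is reported with its chromosome.
.load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- genome
  } else if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
             file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    # FASTA descriptions may carry trailing comments; keep the first word
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(genome)) {
    .stop_if(is.null(names(genome)) || any(!nzchar(names(genome))),
             "genome character vector must be named by chromosome")
    for (chrom in names(genome)) {
      bad <- regexpr("[^ACGTNacgtn]", genome[[chrom]])
      .stop_if(bad > 0L, sprintf(
        "invalid character '%s' in chromosome '%s' at position %d",
        substr(genome[[chrom]], bad, bad), chrom, as.integer(bad)))
    }
    seqs <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    stop("genome must be a DNAStringSet, a named character vector, ",
         "or a FASTA path", call. = FALSE)
  }
  .stop_if(anyDuplicated(names(seqs)) > 0L, "duplicate chromosome names in genome")
  # DNAStringSet admits IUPAC ambiguity codes; reject anything beyond ACGTN
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")), drop = FALSE]
  if (any(extra > 0)) {
    i <- which(rowSums(extra) > 0)[1L]
    lets <- colnames(extra)[extra[i, ] > 0]
    pos <- regexpr(sprintf("[%s]", paste(lets, collapse = "")),
                   as.character(seqs[[i]]))
    stop(sprintf("invalid character '%s' in chromosome '%s' at position %d",
                 lets[1L], names(seqs)[i], as.integer(pos)), call. = FALSE)
  }
  seqs
}

#' Cut-site positions for one chromosome
#'
#' Returns the modeled fragment boundaries, `motif_start + cut_offset`, for a
#' chromosome of a [gatc_index()].
#'
#' @param index A `gatc_index`.
#' @param chrom Chromosome name.
#' @return Strictly increasing integer vector of 0-based cut-site positions.
#' @export
cut_sites <- function(index, chrom) {
  stopifnot(inherits(index, "gatc_index"))
  .stop_if(!chrom %in% names(index$motif_starts),
           sprintf("unknown chromosome '%s'", chrom))
  sites <- index$motif_starts[[chrom]] + index$cut_offset
  sites[sites < index$chrom_lengths[[chrom]]]
}

#' @export
print.gatc_index <- function(x, ...) {
  cat(sprintf("GATC index: %d chromosome(s), %d motif(s), cut_offset=%d\n",
              length(x$chrom_lengths),
              sum(lengths(x$motif_starts)), x$cut_offset))
  for (chrom in utils::head(names(x$chrom_lengths), 10L)) {
    cat(sprintf("  %s: length %d, %d GATC motifs\n", chrom,
                x$chrom_lengths[[chrom]], length(x$motif_starts[[chrom]])))
  }
  if (length(x$chrom_lengths) > 10L) cat("  ...\n")
  invisible(x)
}

#' Serialize / read a GATC index as TSV
#'
#' The index is stored as a two-column TSV (`chrom`, `motif_start`) preceded
#' by comment lines recording the cut offset and chromosome lengths, so the
#' file round-trips exactly.
#'
#' @param index A `gatc_index`.
#' @param path Output file path.
#' @return `write_gatc_index` returns `path` invisibly; `read_gatc_index`
#'   returns a `gatc_index`.
#' @export
write_gatc_index <- function(index, path) {
  stopifnot(inherits(index, "gatc_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cut_offset=%d", index$cut_offset), con)
  writeLines(sprintf("# chrom_length\t%s\t%d", names(index$chrom_lengths),
                     as.integer(index$chrom_lengths)), con)
  writeLines("chrom\tmotif_start", con)
  for (chrom in names(index$motif_starts)) {
    st <- index$motif_starts[[chrom]]
    if (length(st)) writeLines(paste(chrom, st, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_gatc_index
#' @export
read_gatc_index <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  off <- sub("^# cut_offset=", "", grep("^# cut_offset=", hdr, value = TRUE))
  .stop_if(length(off) != 1L, "missing cut_offset header in index file")
  len_lines <- grep("^# chrom_length\t", hdr, value = TRUE)
  lens <- do.call(rbind, strsplit(sub("^# chrom_length\t", "", len_lines), "\t"))
  chrom_lengths <- stats::setNames(as.integer(lens[, 2L]), lens[, 1L])

  body <- lines[!grepl("^#", lines)]
  .stop_if(length(body) < 1L || body[1L] != "chrom\tmotif_start",
           "malformed index file: missing column header")
  body <- body[-1L]
  motif_starts <- stats::setNames(
    rep(list(integer(0)), length(chrom_lengths)), names(chrom_lengths))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    chrom <- vapply(parts, `[[`, "", 1L)
    pos <- as.integer(vapply(parts, `[[`, "", 2L))
    sp <- split(pos, chrom)
    for (nm in names(sp)) motif_starts[[nm]] <- as.integer(sp[[nm]])
  }
  structure(list(chrom_lengths = chrom_lengths, motif_starts = motif_starts,
                 cut_offset = as.integer(off)),
            class = "gatc_index")
}
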
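#' Read a gene annotation from a BED6 file
#'
#' Genes are supplied in the 6-column BED dialect (`chrom`, `start`, `end`,
#' `name`, `score`, `strand`), 0-based half-open. The strand-aware
#' transcription start site (TSS) is derived per gene: `start` on the plus
#' strand, `end - 1` (the last base of the half-open interval) on the minus
#' strand.
#'
#' @param path Path to a BED6 file (tab-separated, no header; `track` and
#'   `#` comment lines are skipped).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (all coordinates 0-based; `tss` is a position).
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(validate_genes(data.frame(gene_id = character(0),
                                     chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  .stop_if(any(nf < 6L), sprintf("malformed BED row at line %d: %d field(s), need 6",
                                 lineno[which(nf < 6L)[1L]], nf[nf < 6L][1L]))
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  .stop_if(length(bad) > 0L,
           sprintf("malformed BED row at line %d: non-integer coordinates", lineno[bad[1L]]))
  genes <- data.frame(
    gene_id = vapply(parts, `[[`, "", 4L),
    chrom = vapply(parts, `[[`, "", 1L),
    start = start, end = end,
    strand = vapply(parts, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
  validate_genes(genes, lineno = lineno)
}

#' Validate a gene model table
#'
#' Checks the gene-model invariants (`start < end`, strand in `{+,-}`,
#' unique `gene_id`) and fills in the strand-aware `tss` column.
#'
#' @param genes A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param lineno Optional original file line numbers, for error messages.
#' @return The validated `data.frame` with a `tss` column.
#' @export
validate_genes <- function(genes, lineno = seq_len(nrow(genes))) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  .stop_if(!all(req %in% names(genes)),
           paste("gene table missing column(s):",
                 paste(setdiff(req, names(genes)), collapse = ", ")))
  bad <- which(!genes$strand %in% c("+", "-"))
  .stop_if(length(bad) > 0L,
           sprintf("invalid strand '%s' at line %d (must be + or -)",
                   genes$strand[bad[1L]], lineno[bad[1L]]))
  bad <- which(!(genes$start < genes$end) | genes$start < 0)
  .stop_if(length(bad) > 0L,
           sprintf("invalid interval at line %d: start must satisfy 0 <= start < end",
                   lineno[bad[1L]]))
  dup <- which(duplicated(genes$gene_id))
  .stop_if(length(dup) > 0L,
           sprintf("duplicate gene_id '%s' at line %d",
                   genes$gene_id[dup[1L]], lineno[dup[1L]]))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

#' Write a gene table as BED6
#'
#' @param genes A validated gene `data.frame` (see [read_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  out <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                 genes$end, genes$gene_id, genes$strand)
  writeLines(out, path)
  invisible(path)
}
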
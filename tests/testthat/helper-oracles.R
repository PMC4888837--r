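# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive algorithms (sliding windows, per-read loops,
# dense arrays, all-pairs graphs, exhaustive tail sums) so they share no
# code path with the package internals they check.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# all 0-based positions where the 4-mer starting there equals GATC
oracle_motif_scan <- function(seq) {
  n <- nchar(seq)
  if (n < 4) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - 3)) {
    if (substr(seq, i, i + 3) == "GATC") hits <- c(hits, i - 1L)
  }
  hits
}

# per-read anchor predicate: five-prime end within tol of some cut site
oracle_filter <- function(reads, index, mapq_min = 10, tol = 0) {
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    sites <- index$motif_starts[[reads$chrom[i]]] + index$cut_offset
    sites <- sites[sites < index$chrom_lengths[[reads$chrom[i]]]]
    fp <- if (reads$strand[i] == "+") reads$start[i] else reads$end[i] - 1L
    keep[i] <- reads$mapq[i] > mapq_min &&
      length(sites) > 0 && min(abs(fp - sites)) <= tol
  }
  keep
}

# per-read tally at nearest cut site (leftmost wins ties)
oracle_count <- function(reads, index) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    chrom <- reads$chrom[i]
    sites <- index$motif_starts[[chrom]] + index$cut_offset
    sites <- sites[sites < index$chrom_lengths[[chrom]]]
    fp <- if (reads$strand[i] == "+") reads$start[i] else reads$end[i] - 1L
    d <- abs(fp - sites)
    site <- sites[which.min(d)]  # which.min picks the first (leftmost) tie
    key <- paste(chrom, site)
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# dense per-base coverage accumulation of extension-padded reads
oracle_coverage <- function(reads, chrom_len, extension) {
  cov <- numeric(chrom_len)
  for (i in seq_len(nrow(reads))) {
    s <- max(reads$start[i] - extension, 0L)
    e <- min(reads$end[i] + extension, chrom_len)
    if (s < e) cov[(s + 1):e] <- cov[(s + 1):e] + 1
  }
  cov
}

# transitive-closure clustering of sorted positions under gap <= max_gap
oracle_site_clusters <- function(pos, max_gap) {
  pos <- sort(pos)
  groups <- list()
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= max_gap) cur <- c(cur, p)
    else { groups[[length(groups) + 1]] <- cur; cur <- p }
  }
  groups[[length(groups) + 1]] <- cur
  groups
}

# exhaustive peak enumeration on one chromosome: member predicate, gap
# grouping, then region-level thresholds, all written directly
oracle_peaks <- function(pos, sval, cval, params) {
  cfloor <- pmax(cval, mean(cval))
  member <- sval > 0 &
    (sval + params$pseudocount) / (cfloor + params$pseudocount) >= params$min_fold
  if (!any(member)) return(NULL)
  groups <- oracle_site_clusters(pos[member], params$max_gap)
  rows <- list()
  for (g in groups) {
    start <- min(g); end <- max(g) + 1L
    nr <- sum(sval[pos %in% g])
    cr <- sum(cval[pos >= start & pos < end])
    fold <- (nr + params$pseudocount) / (cr + params$pseudocount)
    if (nr >= params$min_norm_reads && fold >= params$min_fold &&
        length(g) >= params$min_sites) {
      rows[[length(rows) + 1]] <- data.frame(start = start, end = end,
                                             n_sites = length(g),
                                             norm_reads = nr,
                                             control_norm_reads = cr,
                                             fold = fold)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# connected components of the all-pairs interval overlap graph (half-open)
oracle_components <- function(ints) {
  n <- nrow(ints)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && ints$chrom[i] == ints$chrom[j] &&
        ints$start[i] < ints$end[j] && ints$start[j] < ints$end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# triple loop: for each gene, peak, bin — does the relative interval hit it?
oracle_tss_counts <- function(peaks, genes, window, bin_width) {
  n_bins <- 2 * window / bin_width
  counts <- integer(n_bins)
  for (g in seq_len(nrow(genes))) {
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != genes$chrom[g]) next
      tss <- genes$tss[g]
      if (genes$strand[g] == "+") {
        rs <- peaks$start[p] - tss; re <- peaks$end[p] - tss
      } else {
        rs <- tss - peaks$end[p] + 1L; re <- tss - peaks$start[p] + 1L
      }
      for (b in seq_len(n_bins)) {
        lo <- -window + (b - 1) * bin_width
        if (rs < lo + bin_width && re > lo) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# exhaustive upper-tail hypergeometric sum
oracle_hyper_tail <- function(k, universe, n_a, n_b) {
  sum(vapply(k:min(n_a, n_b), function(x) {
    choose(n_a, x) * choose(universe - n_a, n_b - x) / choose(universe, n_b)
  }, numeric(1)))
}

# small random read set over a genome with a given index
random_reads <- function(n, index, read_len = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(index$chrom_lengths)
  chrom <- sample(chroms, n, replace = TRUE)
  len <- index$chrom_lengths[chrom]
  start <- vapply(len, function(L) sample.int(L - read_len, 1L), integer(1))
  data.frame(chrom = chrom, start = start, end = start + read_len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             mapq = sample(0:60, n, replace = TRUE),
             is_duplicate = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

# minimal valid gene table without a genome behind it
toy_genes <- function(n, chrom = "c1", spacing = 5000L, length = 2000L,
                      strand = NULL) {
  start <- seq(0L, by = spacing, length.out = n) + 1500L
  validate_genes(data.frame(
    gene_id = sprintf("g%04d", seq_len(n)), chrom = rep(chrom, n),
    start = start, end = start + length,
    strand = strand %||% sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}
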
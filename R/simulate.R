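#' Simulation configuration
#'
#' Defines the synthetic study: a random genome with GATC motifs planted at
#' geometrically distributed gaps, non-overlapping genes, two DamID factors
#' (A, B) binding configurable sets of target promoters with a configurable
#' cobound fraction, a ΔCTD-like variant binding a subset of the cobound
#' promoters, a Dam-GFP background control, and a pair of knockdown DE
#' tables whose shared-target genes agree in direction with probability
#' `de_concordance`.
#'
#' @param seed Top-level integer seed; every stage derives its own stream
#'   from it (see [derive_seed()]).
#' @param n_chrom Number of chromosomes. Default 1.
#' @param chrom_length Chromosome length in bp. Default 1e6.
#' @param gatc_spacing_mean Mean planted inter-motif gap in bp (geometric).
#'   Default 256. Incidental GATC matches in the random background add
#'   roughly a further 1/256 per bp and are left in place.
#' @param n_genes Number of genes. Default 200.
#' @param gene_length Gene length in bp. Default 2000.
#' @param n_targets_a,n_targets_b Target promoters per factor. Default 50.
#' @param cobound_fraction Fraction of A targets shared with B. Default 0.5.
#' @param delta_ctd_subset_fraction Fraction of shared targets also bound
#'   by the ΔCTD-like variant. Default 0.55.
#' @param enrichment_fold Sampling weight of cut sites inside target
#'   promoters relative to background sites. Default 20.
#' @param reads_per_library Reads emitted per library. Default 1e5.
#' @param read_length Read length in bp. Default 50.
#' @param duplicate_rate Fraction of each library re-emitted as flagged
#'   duplicates. Default 0.1.
#' @param noise_read_fraction Fraction of primary reads placed at
#'   non-GATC-anchored positions, exercising the filter's rejection path.
#'   Default 0 (off); 0.01 is a typical setting when enabled.
#' @param de_concordance Probability a shared-target gene's knockdown
#'   effects agree in sign between the two tables. Default 0.8.
#' @param de_effect_mean Mean true effect magnitude (z-score units) for
#'   target genes. Default 4.
#' @param de_effect_sd SD of true effect magnitudes. Default 1.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 1L, chrom_length = 1e6,
                       gatc_spacing_mean = 256, n_genes = 200L,
                       gene_length = 2000L,
                       n_targets_a = 50L, n_targets_b = 50L,
                       cobound_fraction = 0.5,
                       delta_ctd_subset_fraction = 0.55,
                       enrichment_fold = 20, reads_per_library = 1e5,
                       read_length = 50L, duplicate_rate = 0.1,
                       noise_read_fraction = 0,
                       de_concordance = 0.8, de_effect_mean = 4,
                       de_effect_sd = 1) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              gatc_spacing_mean = gatc_spacing_mean,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              n_targets_a = as.integer(n_targets_a),
              n_targets_b = as.integer(n_targets_b),
              cobound_fraction = cobound_fraction,
              delta_ctd_subset_fraction = delta_ctd_subset_fraction,
              enrichment_fold = enrichment_fold,
              reads_per_library = as.integer(reads_per_library),
              read_length = as.integer(read_length),
              duplicate_rate = duplicate_rate,
              noise_read_fraction = noise_read_fraction,
              de_concordance = de_concordance,
              de_effect_mean = de_effect_mean,
              de_effect_sd = de_effect_sd)
  for (f in c("cobound_fraction", "delta_ctd_subset_fraction",
              "duplicate_rate", "noise_read_fraction", "de_concordance")) {
    .stop_if(cfg[[f]] < 0 || cfg[[f]] > 1,
             sprintf("%s must be in [0, 1]", f))
  }
  stopifnot(cfg$reads_per_library >= 1L, cfg$n_chrom >= 1L,
            cfg$gatc_spacing_mean > 4, cfg$enrichment_fold > 0,
            cfg$read_length >= 1L, cfg$de_effect_sd >= 0)
  if (cfg$gatc_spacing_mean < cfg$read_length) {
    message("sim_config: gatc_spacing_mean below read_length; ",
            "fragments will be shorter than reads")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome and gene annotation
#'
#' Generates random A/C/G/T chromosomes with GATC motifs planted at
#' geometric gaps (mean `gatc_spacing_mean`); incidental GATC matches that
#' arise in the random background are left in place. Genes of fixed length
#' are placed non-overlapping with random strand, each with room for its
#' promoter window inside the chromosome. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A list of class `sim_genome`: `sequences` (named character
#'   vector), `genes` (validated gene table), `index` (the [gatc_index()]
#'   of the generated genome).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "genome"))
  L <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))

  sequences <- vapply(chroms, function(chrom) {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # plant motif starts at geometric gaps with the configured mean spacing
    n_exp <- ceiling(L / config$gatc_spacing_mean * 1.5) + 10L
    gaps <- 4L + stats::rgeom(n_exp, 1 / (config$gatc_spacing_mean - 4))
    starts <- cumsum(c(sample.int(as.integer(config$gatc_spacing_mean), 1L), gaps))
    starts <- starts[starts <= L - 4L]
    for (k in 0:3) base[starts + k] <- c("G", "A", "T", "C")[k + 1L]
    paste(base, collapse = "")
  }, character(1))
  names(sequences) <- chroms

  genes <- .place_genes(config, chroms)
  list_out <- list(sequences = sequences, genes = genes,
                   index = gatc_index(sequences), config = config)
  class(list_out) <- "sim_genome"
  list_out
}

# Non-overlapping gene placement: genes are spread over equal slots, one
# gene per slot, at a uniform offset that keeps the gene and its +/-1.1 kb
# promoter margin inside the slot.
.place_genes <- function(config, chroms) {
  n <- config$n_genes
  if (n == 0L) {
    return(validate_genes(data.frame(gene_id = character(0),
                                     chrom = character(0), start = integer(0),
                                     end = integer(0), strand = character(0))))
  }
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chrom + 1L)))
  margin <- 1200L
  pieces <- lapply(seq_along(chroms), function(ci) {
    ni <- per_chrom[ci]
    if (ni == 0L) return(NULL)
    slot <- config$chrom_length %/% ni
    .stop_if(slot < config$gene_length + 2L * margin,
             "genes cannot be placed without overlap; increase chrom_length or reduce n_genes")
    offset <- sample.int(slot - config$gene_length - 2L * margin, ni,
                         replace = TRUE) + margin
    start <- (seq_len(ni) - 1L) * slot + offset
    data.frame(gene_id = sprintf("g%04d", seq_len(ni) +
                                   c(0L, cumsum(per_chrom))[ci]),
               chrom = chroms[ci], start = as.integer(start),
               end = as.integer(start + config$gene_length),
               strand = sample(c("+", "-"), ni, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  validate_genes(do.call(rbind, pieces))
}

#' Assign factor target promoters and build the simulation ground truth
#'
#' Samples `n_targets_a` target genes for factor A, shares
#' `round(cobound_fraction * n_targets_a)` of them with factor B (topped up
#' to `n_targets_b` from the remaining genes), and marks
#' `round(delta_ctd_subset_fraction * n_shared)` of the shared genes as
#' ΔCTD-variant targets. Target regions are the promoter windows of the
#' target genes.
#'
#' @param genes A validated gene table.
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param promoter A [promoter_params()] defining the planted windows.
#' @return A list of class `sim_truth`: `target_genes` (per-factor gene-id
#'   vectors), `shared_genes`, `target_regions` (per-factor interval
#'   `data.frame`s), `dir_a` (named per-shared-gene true direction in
#'   table A), `genes`.
#' @export
simulate_truth <- function(genes, config, seed = config$seed,
                           promoter = promoter_params()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "truth"))
  n_shared <- round(config$cobound_fraction * config$n_targets_a)
  .stop_if(config$n_targets_a + config$n_targets_b - n_shared > nrow(genes),
           "not enough genes for the requested target counts")
  ids <- genes$gene_id
  shared <- sample(ids, n_shared)
  rest <- setdiff(ids, shared)
  a_only <- sample(rest, config$n_targets_a - n_shared)
  rest <- setdiff(rest, a_only)
  b_only <- sample(rest, config$n_targets_b - n_shared)
  delta <- sample(shared, round(config$delta_ctd_subset_fraction * n_shared))

  target_genes <- list(A = c(shared, a_only), B = c(shared, b_only),
                       deltaCTD = delta, control = character(0))
  win <- promoter_windows(genes, promoter)
  target_regions <- lapply(target_genes, function(g) {
    w <- win[win$gene_id %in% g, , drop = FALSE]
    rownames(w) <- NULL
    w
  })
  structure(list(target_genes = target_genes, shared_genes = shared,
                 target_regions = target_regions,
                 dir_a = stats::setNames(sample(c(-1, 1), n_shared,
                                                replace = TRUE), shared),
                 genes = genes, promoter = promoter),
            class = "sim_truth")
}

#' Simulate a DamID read library
#'
#' Every read's five-prime end is placed exactly at a GATC cut site (unless
#' injected as noise). The control library samples sites uniformly; factor
#' libraries give cut sites inside their target promoter windows a sampling
#' weight of `enrichment_fold` relative to background sites. A
#' `duplicate_rate` fraction of the library is re-emitted from already
#' drawn reads and flagged as duplicates. Strand is random, MAPQ fixed at
#' 60.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] result.
#' @param index The genome's [gatc_index()].
#' @param factor One of `"A"`, `"B"`, `"deltaCTD"`, `"control"`.
#' @param seed Seed; defaults to `config$seed`.
#' @return A read `data.frame` (see [read_sam_reads()]) with exactly
#'   `reads_per_library` rows.
#' @export
simulate_damid_reads <- function(config, truth, index,
                                 factor = c("control", "A", "B", "deltaCTD"),
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"),
            inherits(index, "gatc_index"))
  factor <- match.arg(factor)
  set.seed(derive_seed(seed, paste0("reads:", factor)))
  rl <- config$read_length

  regions <- truth$target_regions[[factor]]
  if (factor != "control" && nrow(regions) == 0L) {
    warning(sprintf("factor '%s' has no target regions; sampling as control",
                    factor))
  }

  # global site table (sites where a read fits on either strand)
  site_tab <- do.call(rbind, lapply(names(index$chrom_lengths), function(chrom) {
    s <- cut_sites(index, chrom)
    s <- s[s >= rl - 1L & s + rl <= index$chrom_lengths[[chrom]]]
    if (length(s) == 0L) return(NULL)
    data.frame(chrom = chrom, site = s, stringsAsFactors = FALSE)
  }))
  .stop_if(is.null(site_tab) || nrow(site_tab) == 0L,
           "genome has no usable GATC cut sites")

  w <- rep(1, nrow(site_tab))
  if (!is.null(regions) && nrow(regions) > 0L) {
    hit <- .overlap_pairs(data.frame(chrom = site_tab$chrom,
                                     start = site_tab$site,
                                     end = site_tab$site + 1L), regions)
    w[unique(hit$i)] <- config$enrichment_fold
  }

  n_total <- config$reads_per_library
  n_dup <- round(config$duplicate_rate * n_total)
  n_primary <- n_total - n_dup
  pick <- sample.int(nrow(site_tab), n_primary, replace = TRUE, prob = w)
  strand <- sample(c("+", "-"), n_primary, replace = TRUE)
  chrom <- site_tab$chrom[pick]
  site <- site_tab$site[pick]

  n_noise <- floor(config$noise_read_fraction * n_primary)
  if (n_noise > 0L) {
    # displace the five-prime end off any cut site
    idx <- seq_len(n_noise)
    for (k in idx) {
      repeat {
        cand <- sample.int(index$chrom_lengths[[chrom[k]]] - rl, 1L) + rl - 1L
        if (!cand %in% cut_sites(index, chrom[k])) break
      }
      site[k] <- cand
    }
  }

  start <- ifelse(strand == "+", site, site - rl + 1L)
  reads <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(start + rl), strand = strand,
                      mapq = 60L,
                      is_duplicate = FALSE, stringsAsFactors = FALSE)
  if (n_dup > 0L) {
    src <- sample.int(n_primary, n_dup, replace = TRUE)
    dup <- reads[src, , drop = FALSE]
    dup$is_duplicate <- TRUE
    reads <- rbind(reads, dup)
  }
  rownames(reads) <- NULL
  attr(reads, "input_total") <- nrow(reads)
  reads
}

#' Simulate a pair of correlated knockdown DE tables
#'
#' Shared (cobound) target genes receive true effects in both tables: the
#' direction in table B equals the direction in table A with probability
#' `de_concordance`. Effect magnitudes are drawn as
#' `|N(de_effect_mean, de_effect_sd)|` in z-score units; observed per-gene
#' statistics are `z ~ N(direction * magnitude, 1)` with `log2fc = z / 2`,
#' two-sided normal p-values, and Benjamini-Hochberg adjusted p-values.
#' Non-target genes are null (uniform p-values) in both tables.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] result.
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with DE `data.frame`s `a` and `b` and `de_truth`
#'   (gene_id, is_shared_target, dir_a, dir_b).
#' @export
simulate_de_tables <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(derive_seed(seed, "de"))
  ids <- truth$genes$gene_id
  n <- length(ids)
  shared <- ids %in% truth$shared_genes

  dir_a <- rep(0, n)
  dir_a[shared] <- truth$dir_a[ids[shared]]
  same <- stats::runif(n) < config$de_concordance
  dir_b <- ifelse(same, dir_a, -dir_a)

  mag <- function() {
    m <- rep(0, n)
    m[shared] <- abs(stats::rnorm(sum(shared), config$de_effect_mean,
                                  config$de_effect_sd))
    m
  }
  make_table <- function(dir, magnitude) {
    z <- stats::rnorm(n, dir * magnitude, 1)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(gene_id = ids, log2fc = z / 2, pvalue = p,
               padj = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  }
  list(a = make_table(dir_a, mag()), b = make_table(dir_b, mag()),
       de_truth = data.frame(gene_id = ids, is_shared_target = shared,
                             dir_a = dir_a, dir_b = dir_b,
                             stringsAsFactors = FALSE))
}

#' Simulate a complete DamID study
#'
#' Convenience wrapper generating the genome, GATC index, ground truth,
#' the four read libraries (factors A, B, the ΔCTD-like variant, and the
#' Dam-GFP control) and the DE table pair. With `dir` set, all inputs are
#' also written to disk as plain-text files (FASTA, BED, SAM per library,
#' two DE TSVs, and a JSON ground-truth file).
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param dir Optional output directory.
#' @return A list of class `sim_experiment` with `genome`, `index`,
#'   `truth`, `reads` (named list of read `data.frame`s), `de` and,
#'   when written, `paths`.
#' @export
simulate_damid_experiment <- function(config = sim_config(),
                                      seed = config$seed, dir = NULL) {
  genome <- simulate_genome(config, seed)
  truth <- simulate_truth(genome$genes, config, seed)
  reads <- lapply(stats::setNames(nm = c("A", "B", "deltaCTD", "control")),
                  function(f) simulate_damid_reads(config, truth,
                                                   genome$index, f, seed))
  de <- simulate_de_tables(config, truth, seed)
  out <- list(genome = genome, index = genome$index, truth = truth,
              reads = reads, de = de, config = config, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  genes = file.path(dir, "genes.bed"),
                  truth = file.path(dir, "truth.json"))
    seqs <- Biostrings::DNAStringSet(genome$sequences)
    Biostrings::writeXStringSet(seqs, paths$fasta)
    write_genes(genome$genes, paths$genes)
    for (f in names(reads)) {
      paths[[paste0("sam_", f)]] <- file.path(dir, sprintf("%s.sam", f))
      write_sam(reads[[f]], genome$index$chrom_lengths,
                paths[[paste0("sam_", f)]])
    }
    paths$de_a <- file.path(dir, "de_a.tsv")
    paths$de_b <- file.path(dir, "de_b.tsv")
    write_de_table(de$a, paths$de_a)
    write_de_table(de$b, paths$de_b)
    jsonlite::write_json(list(target_genes = truth$target_genes,
                              shared_genes = truth$shared_genes,
                              target_regions = truth$target_regions),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  class(out) <- "sim_experiment"
  out
}
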
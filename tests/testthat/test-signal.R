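# a tiny fixed genome: cut sites at known positions
fixed_index <- function() gatc_index(c(c1 = "AAGATCAA"))  # cut site 4

read_row <- function(chrom = "c1", start, end = start + 4L, strand = "+",
                     mapq = 30L, dup = FALSE) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             mapq = mapq, is_duplicate = dup, stringsAsFactors = FALSE)
}

test_that("reads are retained iff anchored at a cut site with high MAPQ", {
  idx <- fixed_index()
  expect_identical(nrow(filter_reads(read_row(start = 4L), idx)), 1L)
  expect_identical(nrow(filter_reads(read_row(start = 0L), idx)), 0L)
  # MAPQ threshold is strict: 10 fails, 11 passes
  expect_identical(nrow(filter_reads(read_row(start = 4L, mapq = 10L), idx)), 0L)
  expect_identical(nrow(filter_reads(read_row(start = 4L, mapq = 11L), idx)), 1L)
  # minus-strand anchoring uses the five-prime (rightmost) base
  minus <- read_row(start = 1L, end = 5L, strand = "-")
  expect_identical(nrow(filter_reads(minus, idx)), 1L)
  # unknown chromosome errors by name
  expect_error(filter_reads(read_row(chrom = "c9", start = 4L), idx),
               "'c9' absent")
})

test_that("anchor tolerance and duplicate handling behave as configured", {
  idx <- fixed_index()
  near <- read_row(start = 6L)
  expect_identical(nrow(filter_reads(near, idx)), 0L)
  expect_identical(nrow(filter_reads(near, idx, filter_params(anchor_tolerance = 2L))), 1L)
  dup <- read_row(start = 4L, dup = TRUE)
  expect_identical(nrow(filter_reads(dup, idx)), 1L)
  expect_identical(
    nrow(filter_reads(dup, idx, filter_params(keep_duplicates = FALSE))), 0L)
})

test_that("filtering matches the per-read brute-force oracle on random input", {
  set.seed(101)
  for (rep in 1:4) {
    idx <- gatc_index(c(c1 = random_seq(10000), c2 = random_seq(6000)))
    reads <- random_reads(500, idx)
    got <- filter_reads(reads, idx)
    want <- reads[oracle_filter(reads, idx), , drop = FALSE]
    rownames(want) <- NULL
    expect_identical(got, structure(want, input_total = 500L))
    # idempotence: filtering a filtered set changes nothing
    expect_identical(filter_reads(got, idx)[, ], got[, ])
  }
})

test_that("filter is monotone in tolerance and MAPQ threshold", {
  set.seed(55)
  idx <- gatc_index(c(c1 = random_seq(8000)))
  reads <- random_reads(400, idx)
  n_tol <- vapply(c(0L, 2L, 8L, 32L), function(tol)
    nrow(filter_reads(reads, idx, filter_params(anchor_tolerance = tol))),
    integer(1))
  expect_true(all(diff(n_tol) >= 0))
  n_mapq <- vapply(c(0L, 10L, 30L, 59L), function(q)
    nrow(filter_reads(reads, idx, filter_params(mapq_min = q))), integer(1))
  expect_true(all(diff(n_mapq) <= 0))
})

test_that("per-site counts tally duplicates and conserve read totals", {
  idx <- fixed_index()
  trip <- do.call(rbind, replicate(3, read_row(start = 4L), simplify = FALSE))
  counts <- count_sites(filter_reads(trip, idx), idx)
  expect_identical(counts$count, 3L)
  expect_identical(counts$cut_site, 4L)
  empty <- count_sites(filter_reads(read_row(start = 0L), idx), idx)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "retained_total"), 0L)
})

test_that("counts match an independent per-read tally on random input", {
  set.seed(77)
  idx <- gatc_index(c(c1 = random_seq(10000), c2 = random_seq(5000)))
  reads <- filter_reads(random_reads(600, idx), idx,
                        filter_params(anchor_tolerance = 5L))
  counts <- count_sites(reads, idx)
  want <- oracle_count(reads, idx)
  expect_identical(sum(counts$count), nrow(reads))
  got <- setNames(counts$count, paste(counts$chrom, counts$cut_site))
  expect_identical(sort(names(got)), sort(names(want)))
  expect_true(all(got[names(want)] == unlist(want)))
})

test_that("normalization scales to reads per ten million", {
  mk <- function(total, count) {
    structure(data.frame(chrom = rep("c1", length(count)),
                         cut_site = rep(4L, length(count)), count = count),
              retained_total = total, input_total = total,
              class = c("fragment_counts", "data.frame"))
  }
  expect_equal(normalize_counts(mk(1e7, 50L))$value, 50)
  expect_equal(normalize_counts(mk(1e6, 5L))$value, 50)
  expect_equal(normalize_counts(mk(2e7, 100L))$value, 50)
  expect_error(normalize_counts(mk(0L, integer(0))), "empty library")
})

test_that("normalized tracks always sum to 1e7", {
  set.seed(9)
  for (rep in 1:5) {
    idx <- gatc_index(c(c1 = random_seq(20000)))
    reads <- filter_reads(random_reads(sample(50:2000, 1), idx), idx,
                          filter_params(anchor_tolerance = 50L))
    if (nrow(reads) == 0) next
    track <- normalize_counts(count_sites(reads, idx))
    expect_equal(sum(track$value), 1e7, tolerance = 1e-6)
  }
})

test_that("bedGraph pileups extend, clamp and scale as specified", {
  one <- data.frame(chrom = "c1", start = 2000L, end = 2100L, strand = "+",
                    mapq = 60L, is_duplicate = FALSE)
  bg <- make_bedgraph(one, c(c1 = 10000L), extension = 1000L)
  expect_identical(bg$start, 1000L)
  expect_identical(bg$end, 3100L)
  expect_equal(bg$value, 1e7)  # norm_factor for a 1-read library
  clamp <- data.frame(chrom = "c1", start = 100L, end = 200L, strand = "+",
                      mapq = 60L, is_duplicate = FALSE)
  bgc <- make_bedgraph(clamp, c(c1 = 5000L), extension = 1000L)
  expect_identical(c(bgc$start, bgc$end), c(0L, 1200L))
})

test_that("bedGraph coverage equals a dense per-base accumulation", {
  set.seed(31)
  idx <- gatc_index(c(c1 = random_seq(5000)))
  reads <- random_reads(50, idx)
  bg <- make_bedgraph(reads, c(c1 = 5000L), extension = 300L)
  dense <- oracle_coverage(reads, 5000L, 300L) * (1e7 / 50)
  # expand bedGraph back to per-base and compare; omitted runs are zero
  rebuilt <- numeric(5000)
  for (i in seq_len(nrow(bg))) rebuilt[(bg$start[i] + 1):bg$end[i]] <- bg$value[i]
  expect_equal(rebuilt, dense)
  # intervals are sorted, non-overlapping, non-zero
  expect_true(all(diff(bg$start) > 0))
  expect_true(all(bg$start < bg$end))
  expect_true(all(utils::head(bg$end, -1) <= utils::tail(bg$start, -1) |
                    diff(bg$start) > 0))
  expect_true(all(bg$value > 0))
})

test_that("read mass is conserved through counts and coverage", {
  set.seed(13)
  idx <- gatc_index(c(c1 = random_seq(50000)))
  reads <- filter_reads(random_reads(800, idx, read_len = 20L), idx,
                        filter_params(anchor_tolerance = 100L))
  # keep reads whose extension does not clamp
  ext <- 100L
  reads <- reads[reads$start - ext >= 0 & reads$end + ext <= 50000, ]
  counts <- count_sites(reads, idx)
  expect_identical(sum(counts$count), nrow(reads))
  bg <- make_bedgraph(reads, c(c1 = 50000L), ext)
  mass <- sum(bg$value * (bg$end - bg$start))
  norm_factor <- 1e7 / nrow(reads)
  expect_equal(mass / (norm_factor * (20 + 2 * ext)), nrow(reads))
})

test_that("SAM round trip preserves the fields the pipeline uses", {
  set.seed(17)
  idx <- gatc_index(c(c1 = random_seq(9000), c2 = random_seq(4000)))
  reads <- random_reads(120, idx)
  reads$is_duplicate[sample.int(120, 20)] <- TRUE
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, idx$chrom_lengths, sam)
  back <- read_sam_reads(sam)
  expect_identical(attr(back, "input_total"), 120L)
  for (col in c("chrom", "start", "end", "strand", "mapq", "is_duplicate")) {
    expect_identical(back[[col]], reads[[col]])
  }
})
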
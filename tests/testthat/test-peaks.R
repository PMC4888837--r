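# build a normalized_track directly from site positions and values
mk_track <- function(pos, value, chrom = "c1", retained = 1000L) {
  structure(data.frame(chrom = chrom, pos = as.integer(pos), value = value,
                       stringsAsFactors = FALSE),
            norm_factor = 1e7 / retained, retained_total = retained,
            class = c("normalized_track", "data.frame"))
}

test_that("candidate regions split at gaps and keep single sites", {
  tr <- mk_track(c(100, 600, 5000), c(10, 10, 10))
  cand <- candidate_regions(tr, peak_params(max_gap = 1500L))
  expect_identical(nrow(cand), 2L)
  expect_identical(cand$sites[[1]], c(100L, 600L))
  expect_identical(cand$sites[[2]], 5000L)
  expect_identical(cand$start, c(100L, 5000L))
  expect_identical(cand$end, c(601L, 5001L))
  single <- candidate_regions(mk_track(42, 5), peak_params())
  expect_identical(nrow(single), 1L)
  expect_identical(single$n_sites, 1L)
})

test_that("candidates on different chromosomes never merge", {
  tr <- structure(rbind(mk_track(c(100, 200), c(1, 1), "c1"),
                        mk_track(c(250, 350), c(1, 1), "c2")),
                  class = c("normalized_track", "data.frame"))
  cand <- candidate_regions(tr, peak_params())
  expect_identical(nrow(cand), 2L)
  expect_identical(cand$chrom, c("c1", "c2"))
})

test_that("candidate grouping equals transitive-closure clustering of sites", {
  set.seed(19)
  for (rep in 1:10) {
    pos <- sort(sample.int(100000, sample(5:60, 1)))
    tr <- mk_track(pos, rep(1, length(pos)))
    gap <- sample(c(300L, 1500L, 5000L), 1)
    cand <- candidate_regions(tr, peak_params(max_gap = gap))
    want <- oracle_site_clusters(pos, gap)
    expect_identical(unclass(cand$sites), lapply(want, as.integer))
  }
})

test_that("region thresholds follow the normalized-read floor and fold rule", {
  params <- peak_params()
  # norm_reads just below 50 is rejected regardless of control
  cand <- candidate_regions(mk_track(c(10, 300, 600), c(20, 20, 9.9)), params)
  ps <- suppressWarnings(score_and_filter(cand, mk_track(c(10, 300, 600), c(20, 20, 9.9)),
                                          NULL, params))
  expect_identical(nrow(ps), 0L)
  # norm 100 vs control 49: fold 101/50 = 2.02 >= 2 -> emitted
  sample_tr <- mk_track(c(10, 300, 600), c(40, 40, 20))
  control_tr <- mk_track(c(10, 300, 600), c(16, 16.5, 16.5))
  ps2 <- score_and_filter(candidate_regions(sample_tr, params), sample_tr,
                          control_tr, params)
  expect_identical(nrow(ps2), 1L)
  expect_equal(ps2$norm_reads, 100)
  expect_equal(ps2$fold, 101 / 50)
  # norm 100 vs control 100: fold ~1 -> rejected
  flat <- mk_track(c(10, 300, 600), c(40, 40, 20))
  ps3 <- score_and_filter(candidate_regions(flat, params), flat, flat, params)
  expect_identical(nrow(ps3), 0L)
})

test_that("control reads are summed over all sites inside the region span", {
  params <- peak_params(min_sites = 1L)
  sample_tr <- mk_track(c(100, 400), c(60, 60))
  # control has an extra covered site between the members and one at the
  # half-open end, which must be excluded
  control_tr <- mk_track(c(100, 250, 400, 401), c(5, 7, 9, 100))
  ps <- score_and_filter(candidate_regions(sample_tr, params), sample_tr,
                         control_tr, params)
  expect_equal(ps$control_norm_reads, 5 + 7 + 9)
})

test_that("peak calling is monotone in its thresholds", {
  set.seed(23)
  pos <- sort(sample.int(50000, 40))
  sample_tr <- mk_track(pos, runif(40, 0, 120))
  control_tr <- mk_track(pos, runif(40, 0, 40))
  # thresholds act as pure filters on a fixed candidate structure
  n_peaks <- function(..., min_sites = 1L) {
    p <- peak_params(min_sites = min_sites, ...)
    as.numeric(nrow(score_and_filter(candidate_regions(sample_tr, p),
                                     sample_tr, control_tr, p)))
  }
  expect_true(all(diff(vapply(c(10, 50, 200, 1000), function(x)
    n_peaks(min_norm_reads = x), numeric(1))) <= 0))
  expect_true(all(diff(vapply(c(1.1, 2, 4, 16), function(x)
    n_peaks(min_fold = x), numeric(1))) <= 0))
  expect_true(all(diff(vapply(2:5, function(x)
    n_peaks(min_sites = x), numeric(1))) <= 0))
  # widening the gap can only merge candidate regions, never split them
  n_cand <- vapply(c(200L, 1500L, 20000L), function(x)
    nrow(candidate_regions(sample_tr, peak_params(max_gap = x), control_tr)),
    integer(1))
  expect_true(all(diff(n_cand) <= 0))
})

test_that("emitted peaks equal exhaustive enumeration on small tracks", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    pos <- sort(sample.int(80000, n))
    sval <- round(runif(n, 0, 150), 2)
    sval[sample.int(n, max(1, n %/% 4))] <- 0
    cval <- round(runif(n, 0, 60), 2)
    sample_tr <- mk_track(pos, sval)
    control_tr <- mk_track(pos, cval)
    params <- peak_params(max_gap = sample(c(500L, 1500L, 4000L), 1),
                          min_sites = sample(1:3, 1))
    got <- score_and_filter(candidate_regions(sample_tr, params, control_tr),
                            sample_tr, control_tr, params)
    want <- oracle_peaks(pos, sval, cval, params)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(nrow(got), nrow(want))
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$end, as.integer(want$end))
      expect_identical(got$n_sites, as.integer(want$n_sites))
      expect_equal(got$norm_reads, want$norm_reads)
      expect_equal(got$fold, want$fold)
    }
  }
})

test_that("identical inputs yield byte-identical peak output", {
  set.seed(37)
  cfg <- sim_config(seed = 5, chrom_length = 100000L, n_genes = 20L,
                    n_targets_a = 5L, n_targets_b = 5L,
                    reads_per_library = 10000L)
  sim <- simulate_genome(cfg)
  truth <- simulate_truth(sim$genes, cfg)
  rA <- simulate_damid_reads(cfg, truth, sim$index, "A")
  rC <- simulate_damid_reads(cfg, truth, sim$index, "control")
  p1 <- tempfile(); p2 <- tempfile()
  write_peaks(call_damid_peaks(rA, rC, sim$index, label = "A"), p1)
  write_peaks(call_damid_peaks(rA, rC, sim$index, label = "A"), p2)
  expect_identical(readLines(paste0(p1, ".tsv")), readLines(paste0(p2, ".tsv")))
  expect_identical(readLines(paste0(p1, ".bed")), readLines(paste0(p2, ".bed")))
})

test_that("a library scored against itself yields no peaks", {
  set.seed(41)
  cfg <- sim_config(seed = 9, chrom_length = 100000L, n_genes = 20L,
                    n_targets_a = 5L, n_targets_b = 5L,
                    reads_per_library = 10000L)
  sim <- simulate_genome(cfg)
  truth <- simulate_truth(sim$genes, cfg)
  rA <- simulate_damid_reads(cfg, truth, sim$index, "A")
  expect_identical(nrow(call_damid_peaks(rA, rA, sim$index)), 0L)
  expect_error(call_damid_peaks(rA[0, ], rA, sim$index), "empty library")
})

test_that("a single strongly planted region is recovered at its boundaries", {
  cfg <- sim_config(seed = 3, chrom_length = 200000L, n_genes = 30L,
                    n_targets_a = 1L, n_targets_b = 1L, cobound_fraction = 0,
                    enrichment_fold = 20, reads_per_library = 5000L)
  sim <- simulate_genome(cfg)
  truth <- simulate_truth(sim$genes, cfg)
  rA <- simulate_damid_reads(cfg, truth, sim$index, "A")
  rC <- simulate_damid_reads(cfg, truth, sim$index, "control")
  pk <- call_damid_peaks(rA, rC, sim$index, label = "A")
  tr <- truth$target_regions$A
  hit <- pk$chrom == tr$chrom[1] & pk$start < tr$end[1] & pk$end > tr$start[1]
  expect_true(any(hit))
  # recovered boundaries lie within max_gap of the planted region
  expect_true(all(abs(pk$start[hit] - tr$start[1]) <= 1500))
  expect_true(all(abs(pk$end[hit] - tr$end[1]) <= 1500))
})

test_that("peak sets round-trip through their BED and TSV outputs", {
  set.seed(43)
  ps <- structure(data.frame(chrom = c("c1", "c1", "c2"),
                             start = c(100L, 5000L, 70L),
                             end = c(900L, 6500L, 420L),
                             n_sites = c(4L, 7L, 3L),
                             norm_reads = c(120.5, 77.25, 501),
                             control_norm_reads = c(10, 0, 55.5),
                             fold = c(11.045455, 78.25, 8.8849558),
                             stringsAsFactors = FALSE),
                  label = "NupX", class = c("peak_set", "data.frame"))
  prefix <- tempfile()
  write_peaks(ps, prefix)
  back <- read_peaks(paste0(prefix, ".tsv"))
  expect_identical(attr(back, "label"), "NupX")
  expect_identical(back$start, ps$start)
  expect_equal(back$norm_reads, ps$norm_reads)
  expect_equal(back$fold, ps$fold, tolerance = 1e-6)
})
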
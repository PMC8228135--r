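test_that("Lencz minimum-SNP formula evaluates and floors correctly", {
  # numerator equals denominator -> l = 1
  alpha <- 0.05; ns <- 100; ni <- 10
  het <- 1 - alpha / (ns * ni)
  expect_equal(lencz_min_snps(alpha, ns, ni, het), 1)
  # direct evaluation at the published study dimensions
  expect_equal(lencz_min_snps(0.05, 143593, 131, 0.25), 68)
  # heterozygosity level at which the formula yields 65
  het65 <- 1 - exp(log(0.05 / (143593 * 131)) / 65)
  expect_equal(lencz_min_snps(0.05, 143593, 131, het65 - 1e-6), 65)
  expect_error(lencz_min_snps(0.05, 100, 10, 1.2), "mean_het")
})

test_that("detect_roh finds exactly the qualifying homozygous runs", {
  # all heterozygous -> nothing
  ds <- make_ds(matrix(1L, 2, 10), positions = seq(0, 900, by = 100) * 1000L + 1L)
  expect_equal(nrow(detect_roh(ds, roh_params(min_snps = 2))), 0)
  # 10 homozygous SNPs at 0..900 kb: one segment, 10 SNPs, 900 kb + 1
  pos <- as.integer(seq(0, 900000, by = 100000) + 1L)  # 1-based
  ds2 <- make_ds(matrix(0L, 1, 10), positions = pos)
  segs <- detect_roh(ds2, roh_params(min_length_bp = 500000, min_snps = 5))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 10)
  expect_equal(segs$length_bp, 900001)
  # a heterozygote at 400 kb splits the run; both halves fail the filters
  g <- matrix(0L, 1, 10); g[1, 5] <- 1L
  ds3 <- make_ds(g, positions = pos)
  expect_equal(nrow(detect_roh(ds3, roh_params(min_length_bp = 500000,
                                               min_snps = 5))), 0)
  # a gap larger than max_gap_bp splits a run
  pos2 <- as.integer(c(seq(1, 401000, by = 100000),
                       seq(2000000, 2400000, by = 100000)))
  ds4 <- make_ds(matrix(2L, 1, 10), positions = pos2)
  segs4 <- detect_roh(ds4, roh_params(min_length_bp = 400000, min_snps = 5,
                                      max_gap_bp = 1000000))
  expect_equal(nrow(segs4), 2)
  unsorted <- make_ds(matrix(0L, 1, 2), positions = c(1000L, 2000L))
  unsorted$markers <- unsorted$markers[2:1, ]
  unsorted$genotypes <- unsorted$genotypes[, 2:1, drop = FALSE]
  expect_error(detect_roh(unsorted, roh_params(min_snps = 1)), "sorted")
})

test_that("detect_roh equals the brute-force sub-run enumeration", {
  set.seed(99)
  for (rep in 1:60) {
    m <- sample(5:50, 1)
    pos <- sort(sample.int(5e6, m))
    g <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                prob = c(.4, .15, .4, .05))
    params <- roh_params(min_length_bp = sample(c(2e5, 5e5), 1),
                         max_gap_bp = sample(c(5e5, 1e6), 1),
                         min_snps = sample(2:5, 1),
                         min_density_bp_per_snp = 5e5)
    ds <- make_ds(matrix(g, 1), positions = pos)
    got <- detect_roh(ds, params)
    want <- brute_force_roh(g, pos, params$min_length_bp, params$max_gap_bp,
                            params$min_snps, params$min_density_bp_per_snp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_bp, unname(want[, "start"]))
      expect_equal(got$end_bp, unname(want[, "end"]))
      expect_equal(got$n_snps, unname(want[, "n_snps"]))
    }
  }
})

test_that("raising min_snps or min_length never adds segments", {
  set.seed(7)
  pos <- sort(sample.int(2e7, 300))
  g <- sample(c(0L, 1L, 2L), 300, replace = TRUE, prob = c(.45, .1, .45))
  ds <- make_ds(matrix(g, 1), positions = pos)
  base <- detect_roh(ds, roh_params(min_snps = 3, min_length_bp = 2e5))
  for (ms in c(5, 10)) {
    tighter <- detect_roh(ds, roh_params(min_snps = ms, min_length_bp = 2e5))
    expect_lte(nrow(tighter), nrow(base))
    if (nrow(tighter))
      expect_true(all(tighter$start_bp %in% base$start_bp))
  }
  longer <- detect_roh(ds, roh_params(min_snps = 3, min_length_bp = 1e6))
  expect_lte(nrow(longer), nrow(base))
})

test_that("length classes and distribution percentages are consistent", {
  segs <- data.frame(sample_id = "s1", chromosome = "1",
                     start_bp = 1, end_bp = 3e6, n_snps = 100,
                     length_bp = 3e6)
  cl <- classify_roh(segs)
  expect_equal(cl$segments$class, "2-4")
  expect_equal(cl$summary$distribution_pct[cl$summary$class == "2-4"], 100)
  # shares always total 100 within a group
  set.seed(3)
  segs2 <- data.frame(sample_id = sample(c("a", "b"), 40, TRUE),
                      chromosome = "1", start_bp = 1,
                      length_bp = 10^stats::runif(40, 5.8, 7.6))
  segs2$end_bp <- segs2$length_bp
  segs2$n_snps <- 50
  grp <- c(a = "G1", b = "G2")
  cl2 <- classify_roh(segs2, groups = grp)
  tot <- tapply(cl2$summary$distribution_pct, cl2$summary$group, sum)
  expect_equal(as.numeric(tot), c(100, 100))
})

test_that("froh ratios, monotonicity and modes behave", {
  # no segments -> all zero
  empty <- data.frame(sample_id = character(), chromosome = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric())
  f0 <- froh(empty, 2e9, sample_ids = "s1")
  expect_true(all(f0$per_sample[, -1] == 0))
  # single segment of 1% of the genome
  one <- data.frame(sample_id = "s1", chromosome = "1", start_bp = 1,
                    end_bp = 21995340, n_snps = 1000, length_bp = 21.99534e6)
  f1 <- froh(one, 2199.534e6, sample_ids = "s1")
  expect_equal(f1$per_sample$froh_total, 0.01)
  # cumulative thresholds are non-increasing and per-class sums to total
  set.seed(8)
  segs <- data.frame(sample_id = "s1", chromosome = "1", start_bp = 1,
                     length_bp = 10^stats::runif(30, 5.75, 7.5))
  segs$end_bp <- segs$length_bp; segs$n_snps <- 99
  fc <- froh(segs, 2.2e9, sample_ids = "s1")
  vals <- unlist(fc$per_sample[1, grep("froh_ge", names(fc$per_sample))])
  expect_true(all(diff(vals) <= 1e-12))
  fp <- froh(segs, 2.2e9, sample_ids = "s1", mode = "per_class")
  expect_equal(sum(fp$per_sample[1, grep("froh_class", names(fp$per_sample))]),
               fc$per_sample$froh_total)
  # group summaries: mean and n-1 SD
  segs$sample_id <- rep(c("s1", "s2"), 15)
  fg <- froh(segs, 2.2e9, sample_ids = c("s1", "s2", "s3"),
             groups = c(s1 = "G", s2 = "G", s3 = "G"))
  per <- fg$per_sample$froh_total
  m <- fg$per_group
  expect_equal(m[m$statistic == "mean", "froh_ge_0.5"], mean(per))
  expect_equal(m[m$statistic == "sd", "froh_ge_0.5"], sd(per))
})

test_that("implanted autozygous tracts are recovered", {
  # dense map: 2 chromosomes x 50 Mbp, 1 SNP / 25 kb
  cfg <- sim_config(n_populations = 1, fst = 0.01, n_loci = 4000,
                    n_per_population = 6, n_chromosomes = 2,
                    chromosome_length_bp = 50e6, seed = 21)
  sim <- simulate_balding_nichols(cfg)
  impl <- implant_roh(sim$dataset, target_froh = 0.12, mean_tract_mbp = 8,
                      min_tract_mbp = 2, seed = 22)
  segs <- detect_roh(impl$dataset,
                     roh_params(min_length_bp = 5e5, min_snps = 20,
                                min_density_bp_per_snp = 5e6))
  # base-pair recovery of implanted tracts >= min length
  tracts <- impl$truth$tracts
  covered <- 0; total <- 0
  for (r in seq_len(nrow(tracts))) {
    tr <- tracts[r, ]
    if (tr$length_bp < 5e5) next
    total <- total + tr$length_bp
    hits <- segs[segs$sample_id == tr$sample_id &
                 segs$chromosome == tr$chromosome, , drop = FALSE]
    if (nrow(hits)) {
      ov <- pmin(hits$end_bp, tr$end_bp) - pmax(hits$start_bp, tr$start_bp)
      covered <- covered + sum(pmax(ov, 0))
    }
  }
  expect_gt(covered / total, 0.90)
  # estimated froh within +-10% relative of the implanted level
  fr <- froh(segs, genome_span(impl$dataset)$total_bp,
             sample_ids = impl$dataset$samples$sample_id)
  expect_lt(max(abs(fr$per_sample$froh_total - impl$truth$realized_froh) /
                  impl$truth$realized_froh), 0.10)
})
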
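test_that("PED/MAP and BED/BIM/FAM round-trip to the identical dataset", {
  # A1 ("A") is the minor allele (or tied) at every marker, the orientation
  # the PED reader reconstructs, so dosages survive the full cycle
  geno <- rbind(c(0L, 1L, 2L), c(1L, NA, 0L))
  ds <- make_ds(geno, positions = c(1000L, 5000L, 9000L))
  for (dialect in c("ped_map", "bed_bim_fam")) {
    pref <- tempfile()
    write_plink(ds, pref, dialect)
    back <- read_plink(pref, dialect)
    # read -> write -> read is the identity
    pref2 <- tempfile()
    write_plink(back, pref2, dialect)
    back2 <- read_plink(pref2, dialect)
    expect_identical(back$genotypes, back2$genotypes)
    expect_identical(back$markers, back2$markers)
    expect_identical(back$samples, back2$samples)
    # dosage matrix is preserved (A1 assignment is deterministic)
    expect_identical(unname(back$genotypes), unname(geno))
  }
})

test_that("PED genotype '0 0' becomes a missing call", {
  dir <- tempfile(); dir.create(dir)
  pref <- file.path(dir, "x")
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"), paste0(pref, ".map"))
  writeLines(c("fam1 s1 0 0 0 -9 A A 0 0",
               "fam1 s2 0 0 0 -9 A G G G"), paste0(pref, ".ped"))
  ds <- read_plink(pref, "ped_map")
  expect_true(is.na(ds$genotypes["s1", "m2"]))
  expect_false(anyNA(ds$genotypes["s2", ]))
})

test_that("both dialects written from one matrix read back equal", {
  set.seed(11)
  geno <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 5)
  # orient every column so the counted allele is minor-or-tied, matching the
  # PED reader's deterministic A1 assignment
  for (j in seq_len(ncol(geno))) {
    d <- geno[, j]
    if (mean(d, na.rm = TRUE) > 1) geno[, j] <- 2L - d
  }
  ds <- make_ds(geno, chromosome = rep(c("1", "2"), each = 6))
  p1 <- tempfile(); p2 <- tempfile()
  write_plink(ds, p1, "ped_map")
  write_plink(ds, p2, "bed_bim_fam")
  a <- read_plink(p1, "ped_map")
  b <- read_plink(p2, "bed_bim_fam")
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$markers$position, b$markers$position)
  expect_identical(a$samples, b$samples)
})

test_that("malformed PED lines and dimension mismatches are reported", {
  dir <- tempfile(); dir.create(dir)
  pref <- file.path(dir, "bad")
  writeLines(c("1\tm1\t0\t100"), paste0(pref, ".map"))
  writeLines(c("f s1 0 0 0 -9 A A", "f s2 0 0 0 -9 A"), paste0(pref, ".ped"))
  expect_error(read_plink(pref, "ped_map"), "line 2")
  writeLines(c("f s1 0 0 0 -9 A C", "f s2 0 0 0 -9 G G"), paste0(pref, ".ped"))
  expect_error(read_plink(pref, "ped_map"), "biallelic")
})

test_that("intersect_and_merge keeps common markers and harmonizes alleles", {
  g1 <- rbind(c(0L, 1L, 2L, 0L, 1L), c(2L, 2L, 0L, 1L, 1L))
  ds1 <- make_ds(g1)
  # self-merge: identical marker set, doubled samples
  ds1b <- ds1; ds1b$samples$sample_id <- paste0("t", 1:2)
  m <- intersect_and_merge(list(ds1, ds1b))
  expect_equal(n_markers <- ncol(m$dataset$genotypes), 5)
  expect_equal(nrow(m$dataset$genotypes), 4)
  # partial overlap: 5 and 4 markers sharing 3 -> 3 out
  g2 <- rbind(c(1L, 0L, 2L, 2L), c(0L, 1L, 1L, 0L))
  ds2 <- genotype_dataset(
    g2,
    markers = data.frame(marker_id = c("m2", "m4", "m5", "m9"),
                         chromosome = "1", position = c(2, 4, 5, 9) * 1000L,
                         a1 = "A", a2 = "B"),
    samples = data.frame(sample_id = c("u1", "u2"), group = "g2"))
  m2 <- intersect_and_merge(list(ds1, ds2))
  expect_setequal(m2$dataset$markers$marker_id, c("m2", "m4", "m5"))
  # swapped A1/A2 complements dosages
  ds3 <- ds2
  ds3$markers$a1[1] <- "B"; ds3$markers$a2[1] <- "A"
  m3 <- intersect_and_merge(list(ds1, ds3))
  col <- m3$dataset$genotypes[, "m2"]
  expect_identical(unname(col[3:4]), 2L - unname(g2[, 1]))
  # marker set is commutative in input order
  m4 <- intersect_and_merge(list(ds2, ds1))
  expect_setequal(m4$dataset$markers$marker_id,
                  m2$dataset$markers$marker_id)
  expect_error(intersect_and_merge(list(ds1)), "at least 2")
})

test_that("disjoint marker sets give an explicit empty-intersection error", {
  ds1 <- make_ds(rbind(c(0L, 1L), c(2L, 1L)))
  ds2 <- genotype_dataset(
    rbind(c(0L, 1L), c(2L, 1L)),
    markers = data.frame(marker_id = c("x1", "x2"), chromosome = "1",
                         position = c(100L, 200L), a1 = "A", a2 = "B"),
    samples = data.frame(sample_id = c("u1", "u2"), group = "g"))
  expect_error(intersect_and_merge(list(ds1, ds2)), "empty")
})

test_that("missingness filter removes strictly-above-threshold units only", {
  # clean data passes untouched
  ds <- make_ds(matrix(1L, 4, 10))
  r <- filter_missingness(ds, 0.10, 0.10)
  expect_equal(r$report$n_samples_out, 4)
  expect_equal(r$report$n_markers_out, 10)
  expect_equal(r$report$removed$samples_missingness, 0)
  # one sample at 11% missing crosses the 10% threshold; one at exactly 10%
  # is retained (PLINK convention)
  g <- matrix(0L, 10, 100)
  g[1, 1:11] <- NA           # 11%
  g[2, 1:10] <- NA           # exactly 10%
  ds2 <- make_ds(g)
  r2 <- filter_missingness(ds2, 0.10, 0.50)
  expect_equal(r2$report$n_samples_out, 9)
  expect_false("s1" %in% r2$dataset$samples$sample_id)
  expect_true("s2" %in% r2$dataset$samples$sample_id)
  # accounting reconciles by construction
  expect_equal(r2$report$n_samples_in - r2$report$removed$samples_missingness,
               r2$report$n_samples_out)
})

test_that("missingness filtering is idempotent at fixed thresholds", {
  set.seed(42)
  g <- matrix(sample(c(0:2, NA), 600, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 12, 50)
  ds <- make_ds(g)
  r1 <- filter_missingness(ds, 0.15, 0.15)
  r2 <- filter_missingness(r1$dataset, 0.15, 0.15)
  expect_identical(r1$dataset$genotypes, r2$dataset$genotypes)
})

test_that("all-removed filters raise errors", {
  g <- matrix(NA_integer_, 3, 4)
  g[, 1] <- 0L
  expect_error(filter_missingness(make_ds(g), 0.05, 0.05), "all samples")
})

test_that("genome_span sums per-chromosome max-min", {
  ds <- make_ds(rbind(c(0L, 0L), c(2L, 2L)), positions = c(1000L, 1001000L))
  expect_equal(genome_span(ds)$total_bp, 1000000)
  ds2 <- make_ds(matrix(0L, 2, 4), positions = c(1e6, 6e6, 2e6, 9e6),
                 chromosome = c("1", "1", "2", "2"))
  expect_equal(genome_span(ds2)$total_bp, 12e6)
  # 38-chromosome fixture equals the brute-force sum
  set.seed(5)
  chrom <- as.character(rep(1:38, each = 5))
  pos <- as.integer(unlist(lapply(1:38, function(i) sort(sample.int(6e7, 5)))))
  ds3 <- make_ds(matrix(0L, 2, length(pos)), positions = pos,
                 chromosome = chrom)
  manual <- sum(vapply(split(pos, rep(1:38, each = 5)),
                       function(p) max(p) - min(p), 0))
  expect_equal(genome_span(ds3)$total_bp, manual)
  # single-marker chromosome contributes 0 with a warning
  ds4 <- make_ds(matrix(0L, 2, 3), positions = c(1e3, 2e6, 5e5),
                 chromosome = c("1", "1", "2"))
  expect_warning(sp <- genome_span(ds4), "span 0")
  expect_equal(sp$total_bp, 2e6 - 1e3)
})
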
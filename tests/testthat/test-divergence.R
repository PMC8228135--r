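test_that("allele frequencies match direct allele counting", {
  ds <- make_ds(rbind(0L, 1L, 2L))
  af <- allele_freqs(ds)
  expect_equal(unname(af$freq[1, 1]), 0.5)
  expect_equal(unname(af$n_alleles[1, 1]), 6L)
  # all-missing marker is flagged missing
  g <- rbind(c(0L, NA), c(1L, NA))
  af2 <- allele_freqs(make_ds(g))
  expect_true(is.na(af2$freq[1, 2]))
  expect_equal(unname(af2$n_alleles[1, 2]), 0L)
  # random fixture equals brute-force counting
  set.seed(31)
  g3 <- matrix(sample(c(0:2, NA), 20 * 50, TRUE, prob = c(.3, .3, .3, .1)),
               20, 50)
  grp <- rep(c("x", "y"), each = 10)
  af3 <- allele_freqs(make_ds(g3, groups = grp))
  for (k in c("x", "y")) for (j in sample(50, 8)) {
    col <- g3[grp == k, j]
    col <- col[!is.na(col)]
    want <- if (length(col)) sum(col) / (2 * length(col)) else NA_real_
    expect_equal(unname(af3$freq[k, j]), want)
  }
})

test_that("Nei distances match hand evaluations and bounds", {
  f <- rbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  expect_equal(unname(nei_distance(f, "nei1972")$matrix[1, 2]), 0)
  expect_equal(unname(nei_distance(f, "nei1983")$matrix[1, 2]), 0)
  # one locus, p = 0.8 vs 0.2: D = -ln(0.32/0.68)
  f2 <- rbind(a = 0.8, b = 0.2)
  expect_equal(unname(nei_distance(f2, "nei1972")$matrix[1, 2]),
               -log(0.32 / 0.68), tolerance = 1e-12)
  # nei1983 in [0,1], nei1972 >= 0, symmetry, zero diagonal
  set.seed(17)
  f3 <- matrix(runif(4 * 40, 0.01, 0.99), 4,
               dimnames = list(letters[1:4], NULL))
  for (meth in c("nei1972", "nei1983")) {
    d <- nei_distance(f3, meth)$matrix
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    if (meth == "nei1983") expect_true(all(d <= 1))
  }
  # opposite fixation under nei1972 -> flagged large value
  f4 <- rbind(a = c(1, 1), b = c(0, 0))
  expect_equal(unname(nei_distance(f4, "nei1972")$matrix[1, 2]), 1e6)
  # missing frequencies are skipped with L adjusted
  f5 <- rbind(a = c(0.8, NA, 0.4), b = c(0.2, 0.5, NA))
  expect_equal(unname(nei_distance(f5, "nei1972")$matrix[1, 2]),
               -log(0.32 / 0.68))
})

test_that("Weir-Cockerham theta has the right fixed points", {
  set.seed(23)
  # identical generating frequencies -> theta about 0
  p <- runif(800, 0.2, 0.8)
  g1 <- matrix(rbinom(40 * 800, 2, rep(p, each = 40)), 40)
  g2 <- matrix(rbinom(40 * 800, 2, rep(p, each = 40)), 40)
  ds <- make_ds(rbind(g1, g2), groups = rep(c("A", "B"), each = 40))
  fst <- wc_fst_pairwise(ds)
  expect_lt(abs(fst$extra$unclipped["A", "B"]), 0.01)
  # fixed difference at every locus -> theta = 1
  gA <- matrix(2L, 5, 20); gB <- matrix(0L, 5, 20)
  ds2 <- make_ds(rbind(gA, gB), groups = rep(c("A", "B"), each = 5))
  expect_equal(unname(wc_fst_pairwise(ds2)$matrix["A", "B"]), 1)
  # monomorphic everywhere -> flagged NA with warning
  ds3 <- make_ds(matrix(2L, 6, 4), groups = rep(c("A", "B"), each = 3))
  expect_warning(f3 <- wc_fst_pairwise(ds3), "monomorphic")
  expect_true(is.na(f3$matrix["A", "B"]))
})

test_that("theta equals the scalar variance-component oracle", {
  set.seed(41)
  for (rep in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1); L <- sample(3:12, 1)
    g1 <- matrix(sample(c(0:2, NA), n1 * L, TRUE, prob = c(.3, .3, .3, .1)),
                 n1, L)
    g2 <- matrix(sample(c(0:2, NA), n2 * L, TRUE, prob = c(.3, .3, .3, .1)),
                 n2, L)
    ds <- make_ds(rbind(g1, g2), groups = rep(c("A", "B"), c(n1, n2)))
    want <- wc_theta_oracle(g1, g2)
    if (!is.finite(want)) next
    got <- wc_fst_pairwise(ds)$extra$unclipped["A", "B"]
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("theta is invariant to swapping allele labels at any locus", {
  set.seed(53)
  g <- matrix(sample(0:2, 160, TRUE), 16, 10)
  ds <- make_ds(g, groups = rep(c("A", "B"), each = 8))
  t0 <- wc_fst_pairwise(ds)$extra$unclipped["A", "B"]
  g2 <- g; g2[, c(2, 5)] <- 2L - g2[, c(2, 5)]
  t1 <- wc_fst_pairwise(make_ds(g2, groups = rep(c("A", "B"), each = 8))
                        )$extra$unclipped["A", "B"]
  expect_equal(t1, t0, tolerance = 1e-12)
})

test_that("theta on Balding-Nichols data tracks the Monte-Carlo expectation", {
  # Monte-Carlo expectation of W&C theta for two independently drifted
  # populations at the same F, from replicate frequency draws at large L
  mc_expectation <- function(F, n_reps = 200, L = 3000, seed = 1) {
    set.seed(seed)
    vals <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      p <- runif(L, 0.05, 0.95)
      p1 <- rbeta(L, p * (1 - F) / F, (1 - p) * (1 - F) / F)
      p2 <- rbeta(L, p * (1 - F) / F, (1 - p) * (1 - F) / F)
      # infinite-sample limit of the estimator (heterozygosity terms
      # cancel between b and c): theta = s2 / (pbar(1-pbar) + s2/2)
      pbar <- (p1 + p2) / 2
      s2 <- (p1 - pbar)^2 + (p2 - pbar)^2
      vals[r] <- sum(s2) / sum(pbar * (1 - pbar) + s2 / 2)
    }
    mean(vals)
  }
  for (F in c(0.05, 0.2)) {
    cfg <- sim_config(n_populations = 2, fst = F, n_loci = 3000,
                      n_per_population = 40, seed = 100 + round(100 * F))
    sim <- simulate_balding_nichols(cfg)
    th <- wc_fst_pairwise(sim$dataset)$matrix[1, 2]
    expect_lt(abs(th - mc_expectation(F)) / mc_expectation(F), 0.15)
  }
})

test_that("row summaries give mean and n-1 SD of the off-diagonal", {
  m <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  m[lower.tri(m)] <- 1:10; m <- m + t(m)
  dm <- dist_matrix(m, "nei1972")
  s <- summarize_vs_group(dm, "A")
  expect_equal(s$mean, mean(m["A", -1]))
  expect_equal(s$sd, sd(m["A", -1]))
  # all-equal row -> SD 0
  m2 <- matrix(0.3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m2) <- 0
  expect_equal(summarize_vs_group(dist_matrix(m2, "ibs"), "a")$sd, 0)
  expect_error(summarize_vs_group(dm, "Z"), "unknown")
})

test_that("combined table carries one method per triangle", {
  m1 <- matrix(0.1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m2 <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m1) <- diag(m2) <- 0
  comb <- combined_distance_table(dist_matrix(m1, "fst_wc"),
                                  dist_matrix(m2, "nei1972"))
  expect_true(all(comb[lower.tri(comb)] == 0.1))
  expect_true(all(comb[upper.tri(comb)] == 0.9))
  expect_equal(unname(attr(comb, "methods")["lower"]), "fst_wc")
})
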
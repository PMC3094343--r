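test_that("sim_config validates its parameters", {
  expect_error(sim_config(fst = 1.2), "fst")
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(causal_effects = c(`999` = 1), n_markers = 100),
               "out of range")
  expect_error(sim_config(causal_effects = 1), "named")
  expect_error(sim_config(sigma_e2 = -1))
})

test_that("simulate_population: degenerate and admixture regimes", {
  # K = 1: every membership row is exactly 1
  cfg <- sim_config(n_accessions = 15, n_subpops = 1, n_markers = 10, seed = 2)
  pop <- simulate_population(cfg)
  expect_equal(unname(pop$Q$memberships), matrix(1, 15, 1))

  # near-zero fst: subpop frequencies hug the ancestral draw's [0.1, 0.9]
  cfg <- sim_config(n_accessions = 5, n_subpops = 3, fst = 1e-6,
                    n_markers = 50, seed = 3)
  P <- simulate_population(cfg)$subpop_allele_freqs
  expect_lt(max(apply(P, 2, function(c) diff(range(c)))), 0.02)

  # tiny alpha: near-pure accessions. Independent Monte Carlo oracle
  # (2e5 draws, cross-checked in log space) gives P(max > 0.99) = 0.871
  # for Dirichlet(0.01, K = 4); assert the generator within the 99% MC
  # interval of that value for 1000 draws.
  cfg <- sim_config(n_accessions = 1000, n_subpops = 4, admix_alpha = 0.01,
                    n_markers = 5, seed = 4)
  Q <- simulate_population(cfg)$Q$memberships
  frac <- mean(apply(Q, 1, max) > 0.99)
  expect_gte(frac, 0.871 - 2.576 * sqrt(0.871 * 0.129 / 1000))
  expect_lte(frac, 0.871 + 2.576 * sqrt(0.871 * 0.129 / 1000))
})

test_that("simulate_markers: fixed and stochastic frequencies", {
  Q <- admixture_q(matrix(c(0.5, 0.5), 4, 2, byrow = TRUE))
  P1 <- matrix(1, 2, 3)
  expect_true(all(simulate_markers(Q, P1, seed = 1)$scores == 1))
  expect_true(all(simulate_markers(Q, 0 * P1, seed = 1)$scores == 0))
  expect_error(simulate_markers(Q, matrix(0.5, 3, 3)), "disagree")

  # realized frequency within 3 binomial SDs of the expected 0.3
  n <- 500
  Qb <- admixture_q(matrix(c(0.6, 0.4), n, 2, byrow = TRUE))
  Pb <- matrix(0.3, 2, 40)
  mk <- simulate_markers(Qb, Pb, seed = 9)
  sd3 <- 3 * sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(mk$allele_freq - 0.3) < sd3))
})

test_that("simulate_phenotypes components are exact bookkeeping", {
  fx <- sim_fixture(n = 40, k = 2, m = 60, seed = 5)
  K <- kinship_jaccard(fx$markers)

  # all-zero variance, no effects: constant phenotype
  cfg0 <- sim_config(n_accessions = 40, n_subpops = 2, n_markers = 60,
                     sigma_g2 = 0, sigma_e2 = 0, seed = 5)
  ph0 <- simulate_phenotypes(fx$markers, fx$Q, K, cfg0)
  expect_equal(diff(range(ph0$phenotypes$values)), 0)

  # components sum to y to machine precision, multi-trait with effects
  cfg <- sim_config(n_accessions = 40, n_subpops = 2, n_markers = 60,
                    causal_effects = c(`3` = 1.2, `10` = -0.5),
                    pop_effects = c(0, 1), sigma_g2 = 0.4, sigma_e2 = 0.8,
                    n_traits = 3, seed = 6)
  ph <- simulate_phenotypes(fx$markers, fx$Q, K, cfg)
  tr <- ph$truth
  expect_equal(tr$pop + tr$marker + tr$polygenic + tr$noise,
               ph$phenotypes$values)

  # identity K: polygenic variance close to sigma_g2 at large n
  n <- 2000
  cfgI <- sim_config(n_accessions = n, n_subpops = 1, n_markers = 5,
                     sigma_g2 = 1, sigma_e2 = 0, seed = 7)
  fxI <- sim_fixture(n = n, k = 1, m = 5, seed = 7)
  phI <- simulate_phenotypes(fxI$markers, fxI$Q, diag(n), cfgI)
  expect_lt(abs(stats::var(phI$truth$polygenic[, 1]) - 1), 0.1)
})

test_that("binarize_ssr encodes per-allele presence columns grouped by locus", {
  calls <- data.frame(accession = c("a1", "a2", "a3", "a3"),
                      locus = "L1", allele = c("A", "B", "A", "B"))
  mk <- binarize_ssr(calls)
  expect_equal(unname(mk$scores[, "L1_A"]), c(1, 0, 1))
  expect_equal(unname(mk$scores[, "L1_B"]), c(0, 1, 1))
  expect_equal(mk$ssr_locus, c("L1", "L1"))

  # monoallelic locus: a single all-1 column
  mono <- data.frame(accession = c("a1", "a2"), locus = "L2", allele = "X")
  expect_equal(unname(binarize_ssr(mono)$scores[, 1]), c(1, 1))

  # study-scale shape: 28 loci x ~7 alleles -> 194 columns
  set.seed(11)
  n_alleles <- c(rep(7, 26), 6, 6)  # 26*7 + 12 = 194
  long <- do.call(rbind, lapply(seq_len(28), function(l) {
    als <- paste0("al", seq_len(n_alleles[l]))
    data.frame(accession = sample(sprintf("a%02d", 1:30), 60, replace = TRUE),
               locus = sprintf("L%02d", l),
               allele = sample(als, 60, replace = TRUE))
  }))
  # ensure every allele is observed at least once
  long <- rbind(long, do.call(rbind, lapply(seq_len(28), function(l)
    data.frame(accession = "a01", locus = sprintf("L%02d", l),
               allele = paste0("al", seq_len(n_alleles[l]))))))
  mk194 <- binarize_ssr(long)
  expect_equal(ncol(mk194$scores), 194L)
  expect_equal(length(unique(mk194$ssr_locus)), 28L)
})

test_that("most_frequent_allele_subset keeps one column per SSR locus", {
  sc <- cbind(a = c(1, 1, 1, 0, 0), b = c(1, 0, 0, 0, 0), c = c(1, 0, 0, 0, 1),
              afl = c(0, 1, 0, 1, 0))
  mk <- marker_matrix(sc, c("SSR", "SSR", "SSR", "AFLP"),
                      c("L1", "L1", "L1", NA))
  out <- most_frequent_allele_subset(mk)
  expect_equal(colnames(out$scores), c("a", "afl"))  # freq 0.6 column kept

  # no SSR columns: identity
  mk2 <- rand_markers(10, 5, seed = 3)
  expect_equal(most_frequent_allele_subset(mk2)$scores, mk2$scores)

  # count arithmetic: total - (ssr_alleles - n_loci)
  fx <- sim_fixture(n = 40, k = 2, m = 20, seed = 8)
  types <- c(rep("AFLP", 12), rep("SSR", 8))
  loci <- c(rep(NA, 12), "L1", "L1", "L1", "L2", "L2", "L3", "L3", "L3")
  mk3 <- marker_matrix(fx$markers$scores, types, loci)
  expect_equal(ncol(most_frequent_allele_subset(mk3)$scores), 20 - (8 - 3))
})

test_that("filter_markers applies the strict symmetric frequency band", {
  n <- 100
  mk <- marker_matrix(sapply(c(0.05, 0.10, 0.11, 0.50, 0.95),
                             function(f) rep(c(1L, 0L), c(f * n, n - f * n))))
  out <- filter_markers(mk, 0.10)
  expect_equal(which(mk$allele_freq %in% out$allele_freq), c(3L, 4L))
  expect_equal(attr(out, "n_dropped"), 3L)

  # idempotence
  expect_equal(filter_markers(out, 0.10)$scores, out$scores)

  # independent recount on a random fixture
  mk2 <- rand_markers(60, 80, p = 0.15, seed = 12)
  out2 <- filter_markers(mk2, 0.10)
  expect_equal(ncol(out2$scores),
               sum(mk2$allele_freq > 0.10 & mk2$allele_freq < 0.90))

  # empty result is an explicit error
  mono <- marker_matrix(matrix(1L, 10, 3))
  expect_error(filter_markers(mono), "no markers pass")
})

test_that("marker/phenotype TSV round trips are lossless and validated", {
  mk <- marker_matrix(matrix(rbinom(25, 1, 0.5), 5, 5),
                      c("AFLP", "AFLP", "SSR", "SSR", "AFLP"),
                      c(NA, NA, "L1", "L1", NA))
  f <- tempfile(fileext = ".tsv")
  write_marker_matrix(mk, f)
  back <- read_marker_matrix(f)
  expect_equal(back$scores, mk$scores)
  expect_equal(back$ssr_locus, mk$ssr_locus)

  ph <- phenotype_table(matrix(rnorm(15), 5, 3))
  fp <- tempfile(fileext = ".tsv")
  write_phenotype_table(ph, fp)
  expect_equal(read_phenotype_table(fp)$values, ph$values)

  # non-binary cell is an error naming the position
  bad <- readLines(f)
  bad[3] <- sub("\t0", "\t2", bad[3])
  writeLines(bad, f)
  expect_error(read_marker_matrix(f), "row 2")

  # missing cell unsupported
  bad[3] <- sub("\t2", "\t", bad[3])
  writeLines(bad, f)
  expect_error(read_marker_matrix(f))

  # duplicated accession id
  mk2 <- mk
  rownames(mk2$scores) <- c("a", "a", "b", "c", "d")
  write_marker_matrix(mk2, f)
  expect_error(read_marker_matrix(f), "duplicated")
})

test_that("generation is deterministic under a fixed config", {
  fx1 <- sim_fixture(n = 30, k = 3, m = 50, seed = 21)
  fx2 <- sim_fixture(n = 30, k = 3, m = 50, seed = 21)
  expect_identical(fx1$Q$memberships, fx2$Q$memberships)
  expect_identical(fx1$markers$scores, fx2$markers$scores)
})

test_that("population shifts confound the trait monotonically", {
  fx <- sim_fixture(n = 150, k = 2, m = 80, seed = 22)
  K <- diag(150)
  r2 <- sapply(c(0, 1, 2), function(shift) {
    cfg <- sim_config(n_accessions = 150, n_subpops = 2, n_markers = 80,
                      pop_effects = c(0, shift), sigma_e2 = 1, seed = 23)
    ph <- simulate_phenotypes(fx$markers, fx$Q, K, cfg)
    stats::cor(ph$phenotypes$values[, 1], fx$Q$memberships[, 1])^2
  })
  expect_true(all(diff(r2) > 0))
})
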
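test_that("simulation is reproducible and respects config invariants", {
  cfg <- sim_config(seed = 11, n_diploids_per_subspecies = 2,
                    chrom_length = 100000L, theta_within = 0.006)
  a <- simulate_haplotypes(cfg)
  b <- simulate_haplotypes(cfg)
  expect_identical(a$hap$pos, b$hap$pos)
  expect_identical(a$hap$alleles, b$hap$alleles)
  expect_identical(a$samples, b$samples)
  expect_true(all(diff(a$hap$pos) > 0))
  expect_equal(ncol(a$hap$alleles), 16)  # 2 species x 2 ssp x 2 dip x 2 hap
})

test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(split_time_subspecies = 2, split_time_species = 1))
  expect_error(sim_config(tract = c(1000L, 5000L)), "causal_pos")
  expect_error(sim_config(tract = c(1000L, 5000L), causal_pos = 9000L),
               "inside tract")
  expect_error(sim_config(tract = c(1000L, 5000L), causal_pos = 2000L,
                          introgression_time = 3), "below split_time_species")
  expect_error(sim_config(introgression_fraction = 1.2))
})

test_that("theta_within = 0 yields zero segregating sites and zero windows", {
  cfg <- sim_config(seed = 3, chrom_length = 50000L, theta_within = 0)
  sim <- simulate_haplotypes(cfg)
  expect_equal(length(sim$hap$pos), 0)
  expect_warning(w <- make_windows(sim$hap), "no windows")
  expect_equal(nrow(w), 0)
})

test_that("within-population diversity scales linearly with theta", {
  thetas <- c(0.002, 0.006, 0.012)
  pis <- sapply(seq_along(thetas), function(k) {
    cfg <- sim_config(seed = 40 + k, n_diploids_per_subspecies = 5,
                      chrom_length = 1000000L, theta_within = thetas[k])
    sim <- simulate_haplotypes(cfg)
    a <- sim$hap$alleles
    L <- cfg$chrom_length
    vals <- c()
    for (ss in c("A1", "A2", "B1", "B2")) {
      cols <- which(startsWith(sim$hap$hap_sample, ss))
      for (i in seq_along(cols)[-length(cols)]) for (j in (i + 1):length(cols)) {
        vals <- c(vals, sum(a[, cols[i]] != a[, cols[j]]) / L)
      }
    }
    mean(vals)
  })
  slope <- coef(lm(pis ~ thetas))[2]
  expect_lt(abs(slope - 1), 0.15)  # E[pi per bp] = theta under this model
})

test_that("forced recent introgression nests every A1 haplotype inside B1", {
  ## deep subspecies split so the donor pool fully coalesces before B2 joins
  cfg <- sim_config(seed = 8, n_diploids_per_subspecies = 2,
                    chrom_length = 100000L, theta_within = 0.006,
                    split_time_subspecies = 3, split_time_species = 4,
                    tract = c(0L, 100000L), introgression_time = 0.005,
                    introgression_fraction = 1, causal_pos = 50000L)
  sim <- simulate_haplotypes(cfg)
  win <- make_windows(sim$hap)
  tr <- window_trees(sim$hap, win)
  wt <- weight_track(tr, quartet_from_samples(sim$hap, sim$samples))
  expect_gt(mean(wt$w_intro), 0.95)
  ## recessive phenotype: all A1 and B1 diploids are affected
  expect_equal(sim$samples$phenotype,
               as.numeric(sim$samples$subspecies %in% c("A1", "B1")))
})

test_that("without a tract the species topology dominates intro windows", {
  cfg <- sim_config(seed = 21, n_diploids_per_subspecies = 2,
                    chrom_length = 400000L, theta_within = 0.006)
  sim <- simulate_haplotypes(cfg)
  win <- make_windows(sim$hap)
  expect_gte(nrow(win), 50)
  tr <- window_trees(sim$hap, win)
  wt <- weight_track(tr, quartet_from_samples(sim$hap, sim$samples))
  top <- apply(wt[, c("w_species", "w_intro", "w_third")], 1, which.max)
  expect_lt(mean(top == 2), mean(top == 1))
})

test_that("frequency simulation matches its drift model edge cases", {
  ## near-zero drift: all populations share the ancestral frequency
  tab <- simulate_frequencies(freq_sim_config(seed = 2, n_sites = 500,
                                              F_drift = 1e-6))
  expect_lt(max(abs(tab$p - rowMeans(tab$p))), 0.01)
  expect_error(freq_sim_config(F_drift = 1.5), "F_drift")
  ## determinism
  t1 <- simulate_frequencies(freq_sim_config(seed = 9, n_sites = 100))
  t2 <- simulate_frequencies(freq_sim_config(seed = 9, n_sites = 100))
  expect_identical(t1$p, t2$p)
})

test_that("fixture write/read round-trips the haplotype matrix bit-exactly", {
  cfg <- sim_config(seed = 5, chrom_length = 60000L, theta_within = 0.004)
  sim <- simulate_haplotypes(cfg)
  d <- withr::local_tempdir()
  files <- write_fixture(sim$hap, sim$samples, d, cfg)
  hm2 <- read_vcf(files["vcf"], mode = "multiallelic", phased = TRUE)
  expect_identical(unname(hm2$alleles), unname(sim$hap$alleles))
  expect_identical(hm2$pos, sim$hap$pos)
  ## byte-identical on rewrite
  f2 <- write_fixture(sim$hap, sim$samples, file.path(d, "again"), cfg)
  expect_identical(readLines(files["vcf"]), readLines(f2["vcf"]))
  st <- read.delim(files["samples"])
  expect_equal(nrow(st), 8)
})
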
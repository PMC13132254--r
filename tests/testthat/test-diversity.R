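test_that("pooled pi closed forms on tiny windows", {
  ## one diploid = 2 allele copies, 10 sites, exactly 1 difference
  g <- matrix(0L, 10, 1)
  g[4, 1] <- 1L                       # heterozygous site: 1 discordant pair
  gm <- geno_matrix("chr1", seq_len(10) * 3L, g, "s1")
  pi <- pooled_pi(gm, window_bp = 1000L)
  expect_equal(pi$pi[1], 1 / 10)
  expect_equal(pi$diff_sum[1], 1)
  expect_equal(pi$comp_sum[1], 10)
})

test_that("invariant sites grow the denominator without touching the numerator", {
  set.seed(8)
  gv <- matrix(sample(0:2, 10 * 6, replace = TRUE), 10, 6)
  gm_var <- geno_matrix("chr1", seq_len(10) * 2L, gv, paste0("s", 1:6))
  pi_var <- pooled_pi(gm_var, window_bp = 1000L)
  ## add 10 fully-called invariant sites in the same window
  gi <- rbind(gv, matrix(0L, 10, 6))
  gm_inv <- geno_matrix("chr1", c(seq_len(10) * 2L, 100L + seq_len(10)),
                        gi, paste0("s", 1:6))
  pi_inv <- pooled_pi(gm_inv, window_bp = 1000L)
  expect_equal(pi_inv$diff_sum, pi_var$diff_sum)
  expect_equal(pi_inv$comp_sum, 2 * pi_var$comp_sum)
  expect_equal(pi_inv$pi, pi_var$pi / 2)
})

test_that("pooled pi with missing data equals the pair-count oracle", {
  set.seed(19)
  g <- matrix(sample(c(0:2, NA), 120 * 8, replace = TRUE,
                     prob = c(0.5, 0.2, 0.15, 0.15)), 120, 8)
  pos <- sort(sample.int(5000L, 120))
  gm <- geno_matrix("chr1", pos, g, paste0("s", 1:8))
  pi <- pooled_pi(gm, window_bp = 1000L)
  o <- oracle_pi(g, pos, 1000L)
  expect_equal(pi$diff_sum, o$diff_sum, tolerance = 1e-12)
  expect_equal(pi$comp_sum, o$comp_sum, tolerance = 1e-12)
  expect_equal(pi$pi, o$pi, tolerance = 1e-12)
})

test_that("pi is 0 for identical haplotypes and ratio-of-sums overall", {
  g <- matrix(2L, 50, 4)   # everyone homozygous alt: no variation
  gm <- geno_matrix("chr1", seq_len(50) * 10L, g, paste0("s", 1:4))
  pi <- pooled_pi(gm, window_bp = 10000L)
  expect_equal(pi$pi[1], 0)
})

test_that("trans-polymorphism rules fire as specified", {
  ## 5 species x 5 diploids each; site 1: 4 species polymorphic, plenty of copies
  sp <- rep(paste0("sp", 1:5), each = 5)
  smap <- setNames(sp, paste0("s", 1:25))
  mk <- function(...) {
    rows <- list(...)
    geno_matrix("chr1", seq_along(rows) * 10L,
                do.call(rbind, rows), paste0("s", 1:25))
  }
  site_poly4 <- c(rep(1L, 20), rep(0L, 5))        # sp1-4 polymorphic (het), sp5 fixed
  site_minor5 <- c(rep(c(1L, 0L, 0L, 0L, 0L), 4), rep(0L, 5))
  ## minor allele copies: 4 species x 1 het = 4... make it exactly 5 copies
  site_minor5[21] <- 1L                            # sp5 also het: 5 species x 1 copy
  gm <- mk(site_poly4, site_minor5)
  tp <- classify_transpoly(gm, smap)
  expect_true(tp$is_transpolymorphic[1])
  expect_equal(tp$rule_fired[1], "i")
  ## minor allele has 5 copies total: fails the >= 6 copies rule
  expect_equal(tp$alt_copies[2], 5)
  expect_false(tp$is_transpolymorphic[2])
})

test_that("with three or fewer species present, all must be polymorphic", {
  smap <- setNames(rep(c("spA", "spB"), each = 3), paste0("s", 1:6))
  both_poly <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L), 1)    # both species het-rich
  one_poly <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 1)     # spB monomorphic
  gm <- geno_matrix("chr1", c(10L, 20L), rbind(both_poly, one_poly),
                    paste0("s", 1:6))
  tp <- classify_transpoly(gm, smap)
  expect_true(tp$is_transpolymorphic[1])
  expect_equal(tp$rule_fired[1], "ii")
  expect_false(tp$is_transpolymorphic[2])
})

test_that("classification matches the rule-by-rule oracle on random tables", {
  set.seed(27)
  n_samp <- 24
  sp <- rep(paste0("sp", 1:6), each = 4)
  smap <- setNames(sp, paste0("s", seq_len(n_samp)))
  g <- matrix(sample(c(0:2, NA), 1000 * n_samp, replace = TRUE,
                     prob = c(0.55, 0.2, 0.15, 0.1)), 1000, n_samp)
  gm <- geno_matrix("chr1", seq_len(1000) * 7L, g, paste0("s", seq_len(n_samp)))
  cfg <- analysis_config()
  tp <- classify_transpoly(gm, smap, cfg)
  o <- oracle_transpoly(g, sp, cfg$transpoly_min_poly_species,
                        cfg$transpoly_min_allele_copies)
  expect_identical(tp$is_transpolymorphic, o)
  ## invariant to sample order
  perm <- sample(n_samp)
  gm2 <- geno_matrix("chr1", gm$pos, g[, perm], paste0("s", seq_len(n_samp))[perm])
  tp2 <- classify_transpoly(gm2, smap, cfg)
  expect_identical(tp2$is_transpolymorphic, tp$is_transpolymorphic)
})

test_that("per-window transpoly counts are order-invariant and complete", {
  tp <- data.frame(pos = c(500L, 1500L, 2500L, 3500L),
                   is_transpolymorphic = c(TRUE, FALSE, TRUE, TRUE))
  out <- transpoly_window_counts(tp, window_bp = 2000L)
  expect_equal(out$n_transpoly, c(1L, 2L))
  out2 <- transpoly_window_counts(tp[sample(4), ], window_bp = 2000L)
  expect_equal(out2$n_transpoly, out$n_transpoly)
  ## no transpolymorphic sites -> zeros
  tp0 <- data.frame(pos = c(100L, 900L), is_transpolymorphic = c(FALSE, FALSE))
  expect_equal(transpoly_window_counts(tp0, 1000L)$n_transpoly, 0L)
})

test_that("deep splits without introgression leave almost no trans-species polymorphism", {
  cfg <- sim_config(seed = 66, n_diploids_per_subspecies = 4,
                    chrom_length = 300000L, theta_within = 0.006)
  sim <- simulate_haplotypes(cfg)
  gm <- as_genotypes(sim$hap)
  smap <- setNames(sim$samples$species, sim$samples$sample)
  tp <- classify_transpoly(gm, smap)
  expect_lt(mean(tp$is_transpolymorphic), 0.05)
})
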
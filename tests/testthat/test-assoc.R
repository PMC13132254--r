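test_that("rho-squared closed forms and tie handling match the midrank oracle", {
  expect_equal(rho2(c(0, 0, 2, 2), c(0, 0, 1, 1)), 1)
  expect_equal(rho2(c(0, 2, 0, 2), c(0, 0, 1, 1)), 0)
  expect_true(is.na(rho2(c(1, 1, 1, 1), c(0, 0, 1, 1))))   # constant genotype
  set.seed(101)
  for (rep in 1:20) {
    g <- sample(0:2, 30, replace = TRUE)
    y <- sample(c(0, 0.5, 1), 30, replace = TRUE)
    g[sample(30, 3)] <- NA
    if (length(unique(na.omit(g))) < 2) next
    expect_equal(rho2(g, y), oracle_rho2(g, y), tolerance = 1e-12)
  }
})

test_that("rho-squared is invariant under strictly monotone recoding", {
  set.seed(7)
  g <- sample(0:2, 40, replace = TRUE)
  y <- sample(c(0, 0.5, 1), 40, replace = TRUE)
  base <- rho2(g, y)
  expect_equal(rho2(g * 10 + 3, y), base, tolerance = 1e-12)
  expect_equal(rho2(g, exp(y)), base, tolerance = 1e-12)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(1e6, 0.05), 5e-8)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  n <- c(1, 10, 100, 1e4)
  expect_true(all(diff(sapply(n, bonferroni_threshold)) < 0))
  expect_error(bonferroni_threshold(0), "at least 1")
})

test_that("trend-test scan flags degenerate SNPs and recovers a planted causal", {
  ## monomorphic SNP -> p = 1, flagged
  g <- rbind(rep(1L, 10), c(rep(0L, 5), rep(2L, 5)))
  gm <- geno_matrix("chr1", c(10L, 20L), g, paste0("s", 1:10))
  y <- c(rep(0, 5), rep(1, 5))
  sc <- association_scan(gm, y)
  expect_equal(sc$p_value[1], 1)
  expect_true(sc$flagged[1])
  expect_lt(sc$p_value[2], 0.01)
  expect_error(association_scan(gm, rep(1, 10)), "nonconstant")
  ## fewer than 3 called samples -> p = 1, flagged
  g3 <- matrix(c(0L, 2L, NA, NA), 1)
  gm3 <- geno_matrix("chr1", 10L, g3, paste0("s", 1:4))
  sc3 <- association_scan(gm3, c(0, 1, 0, 1))
  expect_equal(sc3$p_value, 1)
  expect_true(sc3$flagged)
})

test_that("null scan p-values are uniform (KS) on permuted phenotypes", {
  set.seed(12)
  n <- 500; ns <- 1000
  g <- matrix(rbinom(n * ns, 2, runif(ns, 0.1, 0.9)), ns, n)
  y <- rep(c(0, 1), length.out = n)[sample(n)]   # permuted labels
  gm <- geno_matrix("chr1", seq_len(ns) * 10L, g, paste0("s", seq_len(n)))
  sc <- association_scan(gm, y)
  ks <- suppressWarnings(stats::ks.test(sc$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fully-associated intervals follow the 1-based inclusive convention", {
  tab <- data.frame(pos = c(100L, 500L, 900L),
                    p_value = c(1e-9, 1e-9, 0.5),
                    minus_log10_p = c(9, 9, 0.3),
                    rho2 = c(1, 1, 0.2),
                    significant = c(TRUE, TRUE, FALSE),
                    fully_associated = c(TRUE, TRUE, FALSE))
  iv <- fully_associated_interval(tab)
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 500L)
  expect_equal(iv$length_bp, 401L)
  expect_equal(iv$n_snps, 2L)
  ## single fully-associated SNP: 1-bp interval
  tab1 <- tab; tab1$fully_associated <- c(TRUE, FALSE, FALSE)
  expect_equal(fully_associated_interval(tab1)$length_bp, 1L)
  tab0 <- tab; tab0$fully_associated <- FALSE
  expect_warning(iv0 <- fully_associated_interval(tab0), "no fully associated")
  expect_equal(iv0$n_snps, 0L)
})

test_that("assoc table ties rho2, Bonferroni and full association together", {
  set.seed(3)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  causal <- ifelse(y == 1, 2L, 0L)
  g <- rbind(matrix(rbinom(5 * n, 2, 0.4), 5, n), causal)
  gm <- geno_matrix("chr1", c(1:5 * 10L, 100L), g, paste0("s", 1:n))
  sc <- association_scan(gm, y)
  tab <- assoc_table(gm, sc, y)
  expect_equal(attr(tab, "bonferroni"), 0.05 / 6)
  expect_equal(tab$rho2[6], 1)
  expect_true(tab$fully_associated[6])
  ## fully associated implies significant here (non-degenerate design)
  expect_true(all(!tab$fully_associated | tab$significant))
  expect_true(all(tab$minus_log10_p <= 320))
})

test_that("genotype matrix export clusters samples reproducibly", {
  set.seed(90)
  n <- 12
  g <- rbind(matrix(rbinom(3 * n, 2, 0.5), 3, n))
  gm <- geno_matrix("chr1", c(10L, 20L, 30L), g, sprintf("s%02d", 1:n))
  st <- sample_table(sprintf("s%02d", 1:n), "A", "A1",
                     phenotype = rep(c(0, 1), each = 6))
  tab <- data.frame(pos = gm$pos, minus_log10_p = c(3, 5, 7))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  out1 <- genotype_matrix_export(gm, gm$pos, st, tab, f1)
  ## permuting input sample order leaves the clustered output unchanged
  perm <- sample(n)
  gm2 <- geno_matrix("chr1", gm$pos, g[, perm], sprintf("s%02d", 1:n)[perm])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- genotype_matrix_export(gm2, gm$pos, st, tab, f2)
  expect_identical(out1, out2)
  expect_identical(readLines(f1), readLines(f2))
  ## 2 samples, 1 SNP round-trips through the writer; raw dosages exported
  gm3 <- geno_matrix("chr1", 10L, matrix(c(0L, 2L), 1), c("a", "b"))
  st3 <- sample_table(c("a", "b"), "A", "A1", phenotype = c(0, 1))
  tab3 <- data.frame(pos = 10L, minus_log10_p = 4)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  out3 <- genotype_matrix_export(gm3, 10L, st3, tab3, f3)
  rt <- read.delim(f3)
  expect_equal(rt$pos_10[1:2], c(0L, 2L))
  expect_error(genotype_matrix_export(gm3, integer(0), st3, tab3, f3), "empty")
})

test_that("diagnostic motif scan: single fixed difference, identical groups, 4% boundary", {
  ## two groups differing only at alignment position 15 (A vs C), 30 bp
  base <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  a <- base
  substr(a, 15, 15) <- "T"
  A <- rep(a, 10); B <- rep(base, 10)
  hits <- diagnostic_motif_scan(A, B, 15L, k_range = 6L, mode = "strict")
  diag <- hits[hits$diagnostic, ]
  ## every diagnostic hit overlaps the fixed SNP and separates the groups
  expect_true(nrow(diag) > 0)
  expect_true(all((diag$frac_A == 1 & diag$frac_B == 0) |
                  (diag$frac_B == 1 & diag$frac_A == 0)))
  ## identical groups: nothing diagnostic
  h0 <- diagnostic_motif_scan(B, B, 15L, k_range = 6L, mode = "strict")
  expect_equal(sum(h0$diagnostic), 0)
  ## present in 1 of 25 opposing sequences (4%): relaxed yes, strict no
  B2 <- c(rep(base, 24), a)
  h_strict <- diagnostic_motif_scan(A, B2, 15L, k_range = 6L, mode = "strict")
  h_relax <- diagnostic_motif_scan(A, B2, 15L, k_range = 6L, mode = "relaxed")
  expect_equal(sum(h_strict$diagnostic), 0)
  expect_gt(sum(h_relax$diagnostic), 0)
  ## label-swap symmetry: hits mirror with directions exchanged
  h_ab <- diagnostic_motif_scan(A, B, 15L, k_range = 6:8, mode = "strict")
  h_ba <- diagnostic_motif_scan(B, A, 15L, k_range = 6:8, mode = "strict")
  m_ab <- sort(h_ab$motif[h_ab$diagnostic])
  m_ba <- sort(h_ba$motif[h_ba$diagnostic])
  expect_identical(m_ab, m_ba)
  expect_error(diagnostic_motif_scan(c("ACGT", "ACG"), "ACGT", 1L), "equal length")
})
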
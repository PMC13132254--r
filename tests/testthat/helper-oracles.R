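## Independent brute-force oracles. These deliberately use plain site-by-site
## loops and textbook formulas, sharing no code with the package internals.

## MAF/missingness filter: site-by-site loop.
oracle_filter_keep <- function(geno, maf_min, miss_max) {
  keep <- logical(nrow(geno))
  for (i in seq_len(nrow(geno))) {
    gi <- geno[i, ]
    n <- length(gi)
    called <- gi[!is.na(gi)]
    if (length(called) == 0) { keep[i] <- FALSE; next }
    miss <- (n - length(called)) / n
    af <- sum(called) / (2 * length(called))
    maf <- min(af, 1 - af)
    keep[i] <- maf >= maf_min && miss < miss_max
  }
  keep
}

## p-distance matrix: double loop over haplotype pairs and sites.
oracle_pdist <- function(alleles) {
  n <- ncol(alleles)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      nd <- nc <- 0
      for (s in seq_len(nrow(alleles))) {
        a <- alleles[s, i]; b <- alleles[s, j]
        if (!is.na(a) && !is.na(b)) {
          nc <- nc + 1
          if (a != b) nd <- nd + 1
        }
      }
      d[i, j] <- if (nc == 0) NA_real_ else nd / nc
    }
  }
  d
}

## f4 with weighted delete-one-block jackknife: explicit loops.
oracle_f4 <- function(p, pos, block_bp) {
  use <- !apply(p, 1, anyNA)
  p <- p[use, , drop = FALSE]; pos <- pos[use]
  x <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    x[i] <- (p[i, 1] - p[i, 2]) * (p[i, 3] - p[i, 4])
  }
  n <- length(x)
  est <- sum(x) / n
  bid <- (pos - 1) %/% block_bp
  blocks <- sort(unique(bid))
  g <- length(blocks)
  theta_mj <- m_j <- numeric(g)
  for (k in seq_len(g)) {
    inb <- bid == blocks[k]
    m_j[k] <- sum(inb)
    theta_mj[k] <- mean(x[!inb])
  }
  h_j <- n / m_j
  theta_J <- g * est - sum((1 - m_j / n) * theta_mj)
  tau <- h_j * est - (h_j - 1) * theta_mj
  var_J <- sum((tau - theta_J)^2 / (h_j - 1)) / g
  list(f4 = est, se = sqrt(var_J), n_blocks = g, n_sites = n)
}

## fd / fdM per window: site loops on the ABBA-BABA expressions.
oracle_fd <- function(p, pos, window_bp, min_sites) {
  wid <- (pos - 1) %/% window_bp
  res <- NULL
  for (w in sort(unique(wid))) {
    i <- which(wid == w)
    num <- den <- den_neg <- 0
    ninf <- 0
    for (k in i) {
      r <- p[k, ]
      if (anyNA(r)) next
      if (max(r) > min(r)) ninf <- ninf + 1
      num <- num + (1 - r[1]) * r[2] * r[3] * (1 - r[4]) -
        r[1] * (1 - r[2]) * r[3] * (1 - r[4])
      pd <- max(r[2], r[3])
      den <- den + (1 - r[1]) * pd * pd * (1 - r[4]) -
        r[1] * (1 - pd) * pd * (1 - r[4])
      pn <- max(r[1], r[3])
      den_neg <- den_neg + (1 - pn) * r[2] * pn * (1 - r[4]) -
        pn * (1 - r[2]) * pn * (1 - r[4])
    }
    fd <- if (ninf >= min_sites && num > 0 && den > 0) num / den else NA_real_
    fdM <- if (ninf < min_sites) NA_real_
           else if (num >= 0) { if (den > 0) num / den else NA_real_ }
           else { if (abs(den_neg) > 0) num / abs(den_neg) else NA_real_ }
    res <- rbind(res, data.frame(w = w, fd = fd, fdM = fdM, d_num = num,
                                 n_informative = ninf))
  }
  res
}

## pooled pi: per-site allele-pair counting.
oracle_pi <- function(geno, pos, window_bp) {
  wid <- (pos - 1) %/% window_bp
  res <- NULL
  for (w in sort(unique(wid))) {
    ds <- cs <- 0
    for (i in which(wid == w)) {
      gi <- geno[i, ]
      alleles <- integer(0)
      for (g in gi[!is.na(gi)]) alleles <- c(alleles, c(g >= 1, g >= 2))
      n <- length(alleles)
      if (n < 2) next
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        cs <- cs + 1
        if (alleles[a] != alleles[b]) ds <- ds + 1
      }
    }
    res <- rbind(res, data.frame(w = w, diff_sum = ds, comp_sum = cs,
                                 pi = if (cs > 0) ds / cs else NA_real_))
  }
  res
}

## trans-species polymorphism: rule-by-rule per site.
oracle_transpoly <- function(geno, species, min_poly, min_copies) {
  out <- logical(nrow(geno))
  for (i in seq_len(nrow(geno))) {
    gi <- geno[i, ]
    n_present <- n_poly <- 0
    for (sp in unique(species)) {
      gsp <- gi[species == sp]
      gsp <- gsp[!is.na(gsp)]
      if (length(gsp) == 0) next
      n_present <- n_present + 1
      alt <- sum(gsp); tot <- 2 * length(gsp)
      if (alt > 0 && alt < tot) n_poly <- n_poly + 1
    }
    called <- gi[!is.na(gi)]
    alt_all <- sum(called); ref_all <- 2 * length(called) - alt_all
    poly_rule <- if (n_present > 3) n_poly >= min_poly
                 else n_present > 0 && n_poly == n_present
    out[i] <- poly_rule && alt_all >= min_copies && ref_all >= min_copies
  }
  out
}

## Spearman rho^2 via the explicit midrank formula.
oracle_rho2 <- function(g, y) {
  use <- !is.na(g) & !is.na(y)
  g <- g[use]; y <- y[use]
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rg <- midrank(g); ry <- midrank(y)
  num <- sum((rg - mean(rg)) * (ry - mean(ry)))
  den <- sqrt(sum((rg - mean(rg))^2) * sum((ry - mean(ry))^2))
  (num / den)^2
}

## All permutations of 1..n (for the exhaustive block-order oracle).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

## Small fabricated topology-weight track for permutation tests.
make_toy_track <- function(w_intro, start0 = 0, win_bp = 10000) {
  n <- length(w_intro)
  start <- start0 + (seq_len(n) - 1) * win_bp
  df <- data.frame(chrom = "chr1", start = start, end = start + win_bp,
                   w_species = 1 - w_intro, w_intro = w_intro, w_third = 0,
                   method = "exhaustive")
  df$mid <- (df$start + df$end) / 2
  df$intro95 <- df$w_intro >= 0.95
  class(df) <- c("topo_weight_track", "data.frame")
  df
}
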
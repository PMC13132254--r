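#' Genotype-phenotype trend-test scan
#'
#' Per-SNP score test of genotype dosage \{0,1,2\} against the phenotype code
#' on the samples called at the SNP: the Cochran-Armitage-type statistic
#' `n * r^2` (with `r` the Pearson correlation between dose and phenotype)
#' referred to chi-squared with 1 df, two-sided. This is deliberately plain
#' plumbing downstream of any external mixed-model scan: SNPs monomorphic
#' among called samples, SNPs with a constant phenotype, or SNPs with fewer
#' than 3 called samples get `p = 1` and a flag.
#'
#' @param gm a [geno_matrix()] (normally pre-filtered with [filter_sites()]).
#' @param phenotype numeric phenotype codes, one per sample, `NA` allowed.
#' @return data.frame: `pos, p_value, stat, n_used, flagged`.
#' @export
association_scan <- function(gm, phenotype) {
  stopifnot(inherits(gm, "geno_matrix"),
            length(phenotype) == length(gm$samples))
  if (all(is.na(phenotype)) || length(unique(stats::na.omit(phenotype))) < 2) {
    stop("phenotype must be nonconstant")
  }
  g <- gm$geno
  y <- as.numeric(phenotype)
  n_sites <- nrow(g)
  p <- rep(1, n_sites); stat <- rep(0, n_sites)
  n_used <- integer(n_sites); flagged <- logical(n_sites)
  ok_y <- !is.na(y)
  complete <- !anyNA(g[, ok_y, drop = FALSE])
  if (complete) {
    gg <- g[, ok_y, drop = FALSE]
    yy <- y[ok_y]
    n <- length(yy)
    sg <- rowSums(gg); sg2 <- rowSums(gg^2)
    sy <- sum(yy); sy2 <- sum(yy^2)
    sgy <- as.numeric(gg %*% yy)
    vg <- sg2 - sg^2 / n
    vy <- sy2 - sy^2 / n
    cov <- sgy - sg * sy / n
    mono <- vg <= 0
    r2 <- ifelse(mono, 0, cov^2 / (vg * vy))
    stat <- n * r2
    p <- stats::pchisq(stat, 1, lower.tail = FALSE)
    p[mono] <- 1; stat[mono] <- 0
    flagged <- mono | n < 3
    if (n < 3) p[] <- 1
    n_used <- rep(n, n_sites)
  } else {
    for (i in seq_len(n_sites)) {
      use <- ok_y & !is.na(g[i, ])
      n <- sum(use)
      n_used[i] <- n
      if (n < 3) { flagged[i] <- TRUE; next }
      gi <- g[i, use]; yi <- y[use]
      if (stats::var(gi) == 0 || stats::var(yi) == 0) { flagged[i] <- TRUE; next }
      r <- stats::cor(gi, yi)
      stat[i] <- n * r^2
      p[i] <- stats::pchisq(stat[i], 1, lower.tail = FALSE)
    }
  }
  data.frame(pos = gm$pos, p_value = p, stat = stat,
             n_used = n_used, flagged = flagged)
}

#' Bonferroni-corrected significance threshold
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Squared Spearman rank correlation between genotype and phenotype
#'
#' Midrank-tie Spearman correlation, squared, over the samples called for
#' both variables; both codes are treated as ordinal. Undefined (NA, not 0)
#' when either variable is constant among the used samples or fewer than two
#' samples remain.
#'
#' @param genotypes dosages \{0,1,2\} with `NA` allowed.
#' @param phenotype phenotype codes with `NA` allowed.
#' @return squared Spearman correlation in \[0,1\], or `NA`.
#' @export
rho2 <- function(genotypes, phenotype) {
  use <- !is.na(genotypes) & !is.na(phenotype)
  g <- genotypes[use]; y <- phenotype[use]
  if (length(g) < 2) return(NA_real_)
  if (stats::var(g) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(g, y, method = "spearman")^2
}

#' Assemble the association table
#'
#' Combines the scan p-values with per-SNP rho-squared scores, the Bonferroni
#' significance call, and the fully-associated flag (rho-squared equal to 1
#' on the called samples). `-log10(p)` is capped at 320.
#'
#' @param gm the filtered [geno_matrix()] that was scanned.
#' @param scan result of [association_scan()].
#' @param phenotype phenotype codes per sample.
#' @param cfg an [analysis_config()].
#' @return data.frame of class `assoc_table`: `pos, p_value, minus_log10_p,
#'   rho2, significant, fully_associated`.
#' @export
assoc_table <- function(gm, scan, phenotype, cfg = analysis_config()) {
  thr <- bonferroni_threshold(nrow(scan), cfg$alpha)
  r2 <- vapply(seq_len(nrow(gm$geno)), function(i)
    rho2(gm$geno[i, ], phenotype), numeric(1))
  out <- data.frame(pos = scan$pos, p_value = scan$p_value,
                    minus_log10_p = pmin(-log10(scan$p_value), 320),
                    rho2 = r2,
                    significant = scan$p_value < thr,
                    fully_associated = !is.na(r2) & r2 > 1 - 1e-9)
  attr(out, "bonferroni") <- thr
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Minimal interval containing all fully-associated SNPs
#'
#' 1-based inclusive endpoints, matching printed genomic coordinates; the
#' reported length is `end - start + 1`, so a single fully-associated SNP
#' gives a 1-bp interval.
#'
#' @param tab an [assoc_table()].
#' @return list `start`, `end`, `length_bp`, `n_snps`; all `NA` with
#'   `n_snps = 0` when no SNP is fully associated.
#' @export
fully_associated_interval <- function(tab) {
  pos <- tab$pos[tab$fully_associated]
  if (length(pos) == 0) {
    warning("no fully associated SNPs")
    return(list(start = NA_integer_, end = NA_integer_,
                length_bp = NA_integer_, n_snps = 0L))
  }
  list(start = min(pos), end = max(pos),
       length_bp = max(pos) - min(pos) + 1L, n_snps = length(pos))
}

#' Export a genotype matrix at selected SNPs
#'
#' Samples x SNPs dosage table annotated with the phenotype column and a
#' per-SNP `-log10(p)` row, with samples ordered by average-linkage
#' hierarchical clustering on genotype Hamming distance. Samples are sorted
#' lexicographically before clustering so the output order does not depend on
#' input order.
#'
#' @param gm a [geno_matrix()].
#' @param snp_pos positions of the SNPs to export (must exist in `gm`).
#' @param st a [sample_table()].
#' @param tab an [assoc_table()] supplying `-log10(p)`.
#' @param path output TSV.
#' @return the exported data.frame, invisibly.
#' @export
genotype_matrix_export <- function(gm, snp_pos, st, tab, path) {
  idx <- match(snp_pos, gm$pos)
  if (length(idx) == 0 || anyNA(idx)) stop("empty or unknown SNP set")
  ord0 <- order(gm$samples)
  m <- t(gm$geno[idx, ord0, drop = FALSE])      # samples x SNPs
  rownames(m) <- gm$samples[ord0]
  colnames(m) <- paste0("pos_", gm$pos[idx])
  if (nrow(m) > 2) {
    hd <- matrix(0, nrow(m), nrow(m))
    for (i in seq_len(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        hd[i, j] <- hd[j, i] <- sum(m[i, ] != m[j, ], na.rm = TRUE)
      }
    }
    ord <- stats::hclust(stats::as.dist(hd), method = "average")$order
    m <- m[ord, , drop = FALSE]
  }
  phen <- st$phenotype[match(rownames(m), st$sample)]
  df <- data.frame(sample = rownames(m), phenotype = phen, m,
                   check.names = FALSE, row.names = NULL)
  lp <- tab$minus_log10_p[match(gm$pos[idx], tab$pos)]
  footer <- data.frame(sample = "minus_log10_p", phenotype = NA_real_,
                       t(matrix(lp, dimnames = list(colnames(m)))),
                       check.names = FALSE, row.names = NULL)
  out <- rbind(df, footer)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Diagnostic k-mer motif scan between two homozygote groups
#'
#' Enumerates every k-mer (k in `k_range`) that overlaps at least one fixed
#' SNP position in any sequence of either group, then scores each candidate
#' by the fraction of sequences in each group containing it as a substring
#' anywhere. A hit is diagnostic in strict mode when it occurs in 100% of one
#' group and 0% of the other; relaxed mode allows up to (strictly less than)
#' 5% presence in the opposing group. An optional per-sequence occurrence
#' filter excludes candidates whose median occurrence count in the containing
#' group falls outside `[min_occ, max_occ]`.
#'
#' @param groupA_seqs,groupB_seqs character vectors of aligned equal-length
#'   sequences (homozygotes of the two forms).
#' @param fixed_snp_positions 1-based alignment positions of fixed SNPs.
#' @param k_range integer vector of k-mer lengths (default 6:12).
#' @param mode `"strict"` or `"relaxed"`.
#' @param min_occ,max_occ optional per-sequence occurrence bounds.
#' @return data.frame of class `motif_hits`: `motif, k, frac_A, frac_B,
#'   contains_fixed_snp, diagnostic, direction`.
#' @export
diagnostic_motif_scan <- function(groupA_seqs, groupB_seqs,
                                  fixed_snp_positions, k_range = 6:12,
                                  mode = c("strict", "relaxed"),
                                  min_occ = NULL, max_occ = NULL) {
  mode <- match.arg(mode)
  lens <- unique(nchar(c(groupA_seqs, groupB_seqs)))
  if (length(lens) != 1) stop("sequences must be aligned to equal length")
  L <- lens
  if (any(fixed_snp_positions < 1 | fixed_snp_positions > L)) {
    stop("fixed SNP positions outside the alignment")
  }
  all_seqs <- c(groupA_seqs, groupB_seqs)
  cand <- character(0)
  for (k in k_range) {
    for (p in fixed_snp_positions) {
      lo <- max(1, p - k + 1); hi <- min(p, L - k + 1)
      if (hi < lo) next
      starts <- lo:hi
      for (s in all_seqs) {
        cand <- c(cand, substring(s, starts, starts + k - 1))
      }
    }
  }
  cand <- unique(cand[!grepl("[^ACGTacgt]", cand)])
  if (length(cand) == 0) {
    out <- data.frame(motif = character(0), k = integer(0),
                      frac_A = numeric(0), frac_B = numeric(0),
                      contains_fixed_snp = logical(0),
                      diagnostic = logical(0), direction = character(0))
    class(out) <- c("motif_hits", "data.frame")
    return(out)
  }
  count_in <- function(motif, seqs) {
    vapply(seqs, function(s) {
      n <- 0L; from <- 1L
      repeat {
        hit <- regexpr(motif, substring(s, from), fixed = TRUE)
        if (hit == -1) break
        n <- n + 1L
        from <- from + hit  # advance past the hit start (overlaps allowed)
      }
      n
    }, integer(1), USE.NAMES = FALSE)
  }
  rows <- lapply(cand, function(mo) {
    cA <- count_in(mo, groupA_seqs)
    cB <- count_in(mo, groupB_seqs)
    fA <- mean(cA > 0); fB <- mean(cB > 0)
    diag_strict <- (fA == 1 && fB == 0) || (fB == 1 && fA == 0)
    diag_relax <- (fA == 1 && fB < 0.05) || (fB == 1 && fA < 0.05)
    diagnostic <- if (mode == "strict") diag_strict else diag_relax
    if (diagnostic && (!is.null(min_occ) || !is.null(max_occ))) {
      inn <- if (fA == 1) cA else cB
      mo_med <- stats::median(inn)
      if (!is.null(min_occ) && mo_med < min_occ) diagnostic <- FALSE
      if (!is.null(max_occ) && mo_med > max_occ) diagnostic <- FALSE
    }
    data.frame(motif = mo, k = nchar(mo), frac_A = fA, frac_B = fB,
               contains_fixed_snp = TRUE, diagnostic = diagnostic,
               direction = if (!diagnostic) NA_character_
                           else if (fA == 1) "A" else "B")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motif_hits", "data.frame")
  out
}
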
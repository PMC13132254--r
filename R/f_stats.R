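#' Four-population allele-frequency table
#'
#' @param chrom chromosome name.
#' @param pos integer positions (1-based, increasing).
#' @param p numeric matrix sites x 4 of alternate (or derived) allele
#'   frequencies; `NA` where a population has no calls.
#' @param n_called matrix of called allele counts (may be `Inf` for
#'   frequency-level simulations).
#' @return list of class `freq_table`.
#' @export
freq_table <- function(chrom, pos, p, n_called = NULL) {
  p <- as.matrix(p)
  stopifnot(ncol(p) == 4, length(pos) == nrow(p))
  if (is.null(colnames(p))) colnames(p) <- paste0("pop", 1:4)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("frequencies must lie in [0,1]")
  if (is.null(n_called)) n_called <- matrix(Inf, nrow(p), 4,
                                            dimnames = dimnames(p))
  structure(list(chrom = as.character(chrom)[1], pos = as.integer(pos),
                 p = p, n_called = n_called),
            class = "freq_table")
}

#' Population allele frequencies from a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param pops named list of 4 character vectors of sample ids.
#' @return a [freq_table()] with populations named after `pops`.
#' @export
pop_frequencies <- function(gm, pops) {
  stopifnot(inherits(gm, "geno_matrix"), length(pops) == 4)
  p <- sapply(pops, function(ids) {
    g <- gm$geno[, match(ids, gm$samples), drop = FALSE]
    called <- 2 * rowSums(!is.na(g))
    out <- rowSums(g, na.rm = TRUE) / called
    out[called == 0] <- NA_real_
    out
  })
  n <- sapply(pops, function(ids) {
    g <- gm$geno[, match(ids, gm$samples), drop = FALSE]
    2 * rowSums(!is.na(g))
  })
  p <- matrix(p, nrow = length(gm$pos), dimnames = list(NULL, names(pops)))
  n <- matrix(n, nrow = length(gm$pos), dimnames = list(NULL, names(pops)))
  freq_table(gm$chrom, gm$pos, p, n)
}

#' f4 statistic with weighted block jackknife
#'
#' `f4 = mean over usable sites of (pA - pB)(pC - pD)` for the arrangement
#' `(A, B; C, D)`; sites where any of the four frequencies is undefined are
#' skipped. The standard error comes from a delete-one-block weighted
#' jackknife over nonoverlapping physical blocks (weights proportional to
#' usable sites per block; empty blocks dropped). Arrange the populations so
#' that the sympatric same-location pair are A and C: excess allele sharing
#' between sympatric species then gives a positive f4.
#'
#' @param tab a [freq_table()].
#' @param arrangement character or integer vector of length 4 naming
#'   (A, B, C, D) among the table's populations.
#' @param cfg an [analysis_config()] (jackknife block size).
#' @return list of class `f4_estimate`: `f4, jackknife_se, z, n_blocks,
#'   n_sites, arrangement`.
#' @export
f4_stat <- function(tab, arrangement = 1:4, cfg = analysis_config()) {
  stopifnot(inherits(tab, "freq_table"))
  if (is.character(arrangement)) arrangement <- match(arrangement, colnames(tab$p))
  stopifnot(length(arrangement) == 4, !anyNA(arrangement))
  P <- tab$p[, arrangement, drop = FALSE]
  use <- stats::complete.cases(P)
  if (!any(use)) stop("no site has all four frequencies defined")
  x <- (P[use, 1] - P[use, 2]) * (P[use, 3] - P[use, 4])
  pos <- tab$pos[use]
  n <- length(x)
  est <- mean(x)
  block <- (pos - 1L) %/% cfg$jackknife_block_bp
  bl <- sort(unique(block))
  g <- length(bl)
  if (g < 2) {
    warning("fewer than 2 nonempty jackknife blocks: SE undefined")
    return(structure(list(f4 = est, jackknife_se = NA_real_, z = NA_real_,
                          n_blocks = g, n_sites = n,
                          arrangement = colnames(tab$p)[arrangement]),
                     class = "f4_estimate"))
  }
  m_j <- as.numeric(table(factor(block, levels = bl)))
  sum_all <- sum(x)
  sum_j <- as.numeric(tapply(x, factor(block, levels = bl), sum))
  theta_mj <- (sum_all - sum_j) / (n - m_j)     # delete-one-block estimates
  h_j <- n / m_j
  theta_J <- g * est - sum((1 - m_j / n) * theta_mj)
  tau <- h_j * est - (h_j - 1) * theta_mj       # weighted pseudo-values
  var_J <- sum((tau - theta_J)^2 / (h_j - 1)) / g
  se <- sqrt(var_J)
  structure(list(f4 = est, jackknife_se = se,
                 z = if (se > 0) est / se else NA_real_,
                 n_blocks = g, n_sites = n,
                 arrangement = colnames(tab$p)[arrangement]),
            class = "f4_estimate")
}

#' @export
print.f4_estimate <- function(x, ...) {
  cat(sprintf("f4(%s) = %.6g  SE = %.3g  Z = %.3g  (%d sites, %d blocks)\n",
              paste(x$arrangement, collapse = ", "),
              x$f4, x$jackknife_se, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

## Site-wise ABBA-BABA numerator for derived frequencies (p1, p2, p3, pO).
d_numerator <- function(p1, p2, p3, pO) {
  (1 - p1) * p2 * p3 * (1 - pO) - p1 * (1 - p2) * p3 * (1 - pO)
}

#' Windowed fd and fdM introgression scan
#'
#' Frequencies must be derived-allele frequencies (polarized with
#' [assign_ancestral()] upstream). Per window, the D-statistic numerator is
#' summed over sites; fd divides by the same expression with the donor
#' frequency `max(p2, p3)` substituted for both p2 and p3, and is reported
#' only when the numerator is positive (the raw numerator is always kept).
#' fdM is the signed variant: numerator >= 0 normalizes for a P3-to-P2 donor,
#' numerator < 0 for a P3-to-P1 donor with the sign retained.
#'
#' @param tab a [freq_table()] of derived frequencies, columns interpretable
#'   as the trio arrangement.
#' @param trio vector of 4 (names or indices): (P1, P2, P3, O).
#' @param window_bp window size (default 20 kb).
#' @param min_sites minimum informative sites per window (default 20); below
#'   it the window is masked.
#' @return data.frame of class `fd_track`: `start, end, fd, fdM, d_num,
#'   n_informative`.
#' @export
fd_window <- function(tab, trio = 1:4, window_bp = 20000L, min_sites = 20L) {
  stopifnot(inherits(tab, "freq_table"))
  if (is.character(trio)) trio <- match(trio, colnames(tab$p))
  P <- tab$p[, trio, drop = FALSE]
  use <- stats::complete.cases(P)
  p1 <- P[, 1]; p2 <- P[, 2]; p3 <- P[, 3]; pO <- P[, 4]
  num <- d_numerator(p1, p2, p3, pO)
  pd23 <- pmax(p2, p3)
  den_fd <- d_numerator(p1, pd23, pd23, pO)
  pd13 <- pmax(p1, p3)
  den_neg <- d_numerator(pd13, p2, pd13, pO)   # complete P3->P1 introgression
  informative <- use & apply(P, 1, function(r) max(r) > min(r))
  w0 <- (tab$pos - 1L) %/% as.integer(window_bp)
  wins <- sort(unique(w0))
  out <- do.call(rbind, lapply(wins, function(w) {
    i <- which(w0 == w & use)
    ninf <- sum(w0 == w & informative)
    s_num <- sum(num[i]); s_fd <- sum(den_fd[i]); s_neg <- sum(den_neg[i])
    fd <- if (ninf >= min_sites && s_num > 0 && s_fd > 0) s_num / s_fd else NA_real_
    fdM <- if (ninf < min_sites) NA_real_
           else if (s_num >= 0) { if (s_fd > 0) s_num / s_fd else NA_real_ }
           else { if (abs(s_neg) > 0) s_num / abs(s_neg) else NA_real_ }
    data.frame(start = w * window_bp, end = (w + 1) * window_bp,
               fd = fd, fdM = fdM, d_num = s_num, n_informative = ninf)
  }))
  class(out) <- c("fd_track", "data.frame")
  out
}
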
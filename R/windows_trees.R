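#' Cut a haplotype matrix into nonoverlapping 100-SNP windows
#'
#' Windows are defined in SNP-index space: consecutive blocks of exactly
#' `cfg$window_snps` sites. A trailing remainder shorter than one window is
#' dropped. The bp span of a window is `[pos_first - 1, pos_last)` in 0-based
#' half-open coordinates (i.e., it covers its first through last SNP).
#'
#' @param hm a [hap_matrix()].
#' @param cfg an [analysis_config()].
#' @return data.frame of class `genomic_windows` with columns
#'   `chrom, start, end, first, last, n_sites, mid`.
#' @export
make_windows <- function(hm, cfg = analysis_config()) {
  stopifnot(inherits(hm, "hap_matrix"))
  w <- cfg$window_snps
  n <- length(hm$pos)
  k <- n %/% w
  if (k == 0) {
    warning("fewer than ", w, " sites: no windows")
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), first = integer(0), last = integer(0),
                      n_sites = integer(0), mid = numeric(0))
    class(out) <- c("genomic_windows", "data.frame")
    return(out)
  }
  first <- (seq_len(k) - 1L) * w + 1L
  last <- first + w - 1L
  out <- data.frame(chrom = hm$chrom,
                    start = hm$pos[first] - 1L,   # 0-based half-open
                    end = hm$pos[last],
                    first = first, last = last, n_sites = w)
  out$mid <- (out$start + out$end) / 2
  class(out) <- c("genomic_windows", "data.frame")
  out
}

#' Pairwise p-distances between haplotypes in one window
#'
#' `d(i,j)` = proportion of sites, among those called in both haplotypes,
#' where the alleles differ (any allele mismatch counts 1, so multiallelic
#' codes are handled). Pairs with zero co-called sites yield `NA`, which
#' callers treat as a reason to drop the window.
#'
#' @param hm a [hap_matrix()].
#' @param window one row of a [make_windows()] frame (or a list with
#'   `first`/`last`).
#' @return symmetric numeric matrix over haplotypes.
#' @export
pairwise_distance <- function(hm, window) {
  a <- hm$alleles[window$first:window$last, , drop = FALSE]
  n <- ncol(a)
  if (!anyNA(a)) {
    ## fast path: mismatch counts via crossprod over allele indicator blocks
    mx <- max(a)
    diff <- matrix(0, n, n)
    if (mx == 1L) {
      m <- a
      diff <- crossprod(m, 1 - m); diff <- diff + t(diff)
    } else {
      same <- matrix(0, n, n)
      for (al in 0:mx) {
        ind <- (a == al) * 1
        same <- same + crossprod(ind)
      }
      diff <- nrow(a) - same
    }
    d <- diff / nrow(a)
  } else {
    called <- !is.na(a)
    d <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- called[, i] & called[, j]
        nn <- sum(ok)
        d[i, j] <- d[j, i] <- if (nn == 0) NA_real_
                              else sum(a[ok, i] != a[ok, j]) / nn
      }
    }
    diag(d) <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(hm$hap_id, hm$hap_id)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths
#' are clamped to zero after estimation, keeping the topology.
#'
#' @param D symmetric distance matrix with zero diagonal, >= 4 taxa, no `NA`.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 4) stop("neighbor joining needs at least 4 taxa")
  if (anyNA(D)) stop("distance matrix contains undefined entries")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Build per-window NJ genealogies
#'
#' Applies [pairwise_distance()] and [nj_tree()] to every window; windows
#' whose distance matrix has undefined entries (haplotype pairs with no
#' co-called sites) are dropped and logged in the `dropped` attribute.
#'
#' @param hm a [hap_matrix()].
#' @param windows a [make_windows()] frame.
#' @return list of class `window_tree_track`: `windows` (retained rows),
#'   `trees` (list of `phylo`), `n_sites_used`.
#' @export
window_trees <- function(hm, windows) {
  keep <- logical(nrow(windows))
  trees <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    D <- pairwise_distance(hm, windows[i, ])
    if (anyNA(D)) next
    trees[[i]] <- nj_tree(D)
    keep[i] <- TRUE
  }
  structure(list(windows = windows[keep, , drop = FALSE],
                 trees = trees[keep],
                 n_sites_used = windows$n_sites[keep]),
            class = "window_tree_track",
            dropped = which(!keep))
}

#' Export a window-tree track
#'
#' Writes the trees as one newick per line plus a BED3 of window spans and a
#' TSV index (window id, coordinates, sites used, line number in the newick
#' file).
#'
#' @param track a [window_trees()] result.
#' @param dir output directory.
#' @return named vector of file paths.
#' @export
write_tree_track <- function(track, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nwk <- file.path(dir, "windows.nwk")
  bed <- file.path(dir, "windows.bed")
  tsv <- file.path(dir, "windows.tsv")
  ape::write.tree(do.call(c, track$trees), file = nwk)
  w <- track$windows
  utils::write.table(data.frame(w$chrom, w$start, w$end),
                     bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(window = seq_len(nrow(w)), chrom = w$chrom,
                                start = w$start, end = w$end,
                                n_sites = w$n_sites, tree_line = seq_len(nrow(w))),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  c(newick = nwk, bed = bed, index = tsv)
}
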
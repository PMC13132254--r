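#' Pooled nucleotide diversity in nonoverlapping windows
#'
#' Invariant-site-aware ratio-of-sums estimator: per window,
#' `diff_sum` = number of discordant allele pairs among called alleles summed
#' over sites, `comp_sum` = number of comparable pairs `choose(n_called, 2)`
#' summed over sites with at least two called alleles, and
#' `pi = diff_sum / comp_sum` (not a mean of per-site ratios). The input
#' should include invariant-site records so the denominator reflects
#' sequenced, not just variable, positions; windows with `comp_sum = 0` are
#' `NA`.
#'
#' @param gm a [geno_matrix()] that may contain monomorphic rows.
#' @param window_bp window size in bp (default from `cfg`).
#' @param samples optional subset of sample ids to pool.
#' @param cfg an [analysis_config()].
#' @return data.frame of class `diversity_track`: `start, end, pi, diff_sum,
#'   comp_sum, n_sites_with_data`.
#' @export
pooled_pi <- function(gm, window_bp = NULL, samples = NULL,
                      cfg = analysis_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(window_bp)) window_bp <- cfg$pi_window_bp
  g <- gm$geno
  if (!is.null(samples)) g <- g[, match(samples, gm$samples), drop = FALSE]
  n_called <- 2 * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  diff_site <- alt * (n_called - alt)
  comp_site <- n_called * (n_called - 1) / 2
  has_data <- n_called >= 2
  w0 <- (gm$pos - 1L) %/% as.integer(window_bp)
  wins <- sort(unique(w0))
  if (length(wins) == 0) stop("empty window list")
  rows <- lapply(wins, function(w) {
    i <- which(w0 == w & has_data)
    ds <- sum(diff_site[i]); cs <- sum(comp_site[i])
    data.frame(start = w * window_bp, end = (w + 1) * window_bp,
               pi = if (cs > 0) ds / cs else NA_real_,
               diff_sum = ds, comp_sum = cs,
               n_sites_with_data = length(i))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_track", "data.frame")
  out
}

#' Classify trans-species polymorphisms
#'
#' A biallelic site is trans-polymorphic when (i) at least
#' `cfg$transpoly_min_poly_species` species are polymorphic, applied when more
#' than three species have data at the site, or (ii) all species with data
#' are polymorphic, applied when three or fewer are present; and in either
#' case (iii) every allele is represented by at least
#' `cfg$transpoly_min_allele_copies` copies counted across all species. A
#' species is polymorphic when both alleles occur among its called alleles.
#' Sites with no calls at all are flagged and never trans-polymorphic.
#'
#' @param gm a [geno_matrix()] (biallelic).
#' @param species_map named character vector or list mapping sample id to
#'   species.
#' @param cfg an [analysis_config()].
#' @return data.frame of class `transpoly_table`: per site `pos`,
#'   `n_species_present`, `n_species_polymorphic`, `ref_copies`,
#'   `alt_copies`, `rule_fired` ("i", "ii" or "none"), `is_transpolymorphic`,
#'   `all_missing`.
#' @export
classify_transpoly <- function(gm, species_map, cfg = analysis_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  sp <- unlist(species_map)[gm$samples]
  if (anyNA(sp)) stop("species_map must cover every sample")
  species <- unique(sp)
  if (length(species) < 2) stop("need at least 2 species")
  g <- gm$geno
  n_sites <- nrow(g)
  present <- matrix(FALSE, n_sites, length(species))
  poly <- matrix(FALSE, n_sites, length(species))
  for (k in seq_along(species)) {
    gk <- g[, sp == species[k], drop = FALSE]
    called <- 2 * rowSums(!is.na(gk))
    altk <- rowSums(gk, na.rm = TRUE)
    present[, k] <- called > 0
    poly[, k] <- altk > 0 & altk < called
  }
  n_present <- rowSums(present)
  n_poly <- rowSums(poly)
  called_all <- 2 * rowSums(!is.na(g))
  alt_all <- rowSums(g, na.rm = TRUE)
  ref_all <- called_all - alt_all
  rule_i <- n_present > 3 & n_poly >= cfg$transpoly_min_poly_species
  rule_ii <- n_present <= 3 & n_present > 0 & n_poly == n_present
  copy_ok <- ref_all >= cfg$transpoly_min_allele_copies &
    alt_all >= cfg$transpoly_min_allele_copies
  is_tp <- (rule_i | rule_ii) & copy_ok
  rule <- ifelse(is_tp & rule_i, "i", ifelse(is_tp & rule_ii, "ii", "none"))
  out <- data.frame(pos = gm$pos, n_species_present = n_present,
                    n_species_polymorphic = n_poly,
                    ref_copies = ref_all, alt_copies = alt_all,
                    rule_fired = rule, is_transpolymorphic = is_tp,
                    all_missing = called_all == 0)
  class(out) <- c("transpoly_table", "data.frame")
  out
}

#' Count trans-polymorphic sites per window
#'
#' @param tp a [classify_transpoly()] table.
#' @param window_bp window size in bp (default 10 kb, the scale used for
#'   trans-polymorphism tracks).
#' @return data.frame with `start, end, n_transpoly`.
#' @export
transpoly_window_counts <- function(tp, window_bp = 10000L) {
  w0 <- (tp$pos - 1L) %/% as.integer(window_bp)
  wins <- sort(unique(w0))
  out <- do.call(rbind, lapply(wins, function(w) {
    data.frame(start = w * window_bp, end = (w + 1) * window_bp,
               n_transpoly = sum(tp$is_transpolymorphic[w0 == w]))
  }))
  out
}
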
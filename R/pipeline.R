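#' Quartet specification from a sample table
#'
#' Maps the four subspecies labels onto their haplotype ids in role order
#' (g1 = sspA1, g2 = sspA2, g3 = sspB1, g4 = sspB2). Roles are fixed by the
#' label arguments, never inferred from the data.
#'
#' @param hm a [hap_matrix()].
#' @param st a [sample_table()].
#' @param sspA1,sspA2,sspB1,sspB2 subspecies labels.
#' @return a [quartet_spec()].
#' @export
quartet_from_samples <- function(hm, st, sspA1 = "A1", sspA2 = "A2",
                                 sspB1 = "B1", sspB2 = "B2") {
  haps_of <- function(ss) {
    ids <- st$sample[st$subspecies == ss]
    if (length(ids) == 0) stop("no samples with subspecies ", ss)
    hm$hap_id[hm$hap_sample %in% ids]
  }
  quartet_spec(haps_of(sspA1), haps_of(sspA2), haps_of(sspB1), haps_of(sspB2))
}

#' Simulate-window-weight-test pipeline
#'
#' Chains the full localized-introgression test on one simulated dataset:
#' haplotype simulation, 100-SNP windows, NJ genealogies, quartet topology
#' weights, and the block-permutation intro95 test over a focal region
#' (defaulting to the simulated tract, or the central third of the
#' chromosome when no tract is set).
#'
#' @param sim_cfg a [sim_config()].
#' @param cfg an [analysis_config()].
#' @param focal optional list with `start`, `end` in bp.
#' @param n_perm optional override of `cfg$n_perm`.
#' @param perm_seed seed for the permutation stream (defaults to
#'   `sim_cfg$seed + 500000`).
#' @return list: `sim`, `windows`, `trees`, `weights`, `test`.
#' @export
run_intro_pipeline <- function(sim_cfg, cfg = analysis_config(),
                               focal = NULL, n_perm = NULL,
                               perm_seed = NULL) {
  sim <- simulate_haplotypes(sim_cfg)
  win <- make_windows(sim$hap, cfg)
  if (nrow(win) == 0) stop("simulation produced too few SNPs for one window")
  trees <- window_trees(sim$hap, win)
  q <- quartet_from_samples(sim$hap, sim$samples)
  wt <- weight_track(trees, q, cfg)
  if (is.null(focal)) {
    focal <- if (!is.null(sim_cfg$tract)) {
      list(start = sim_cfg$tract[1], end = sim_cfg$tract[2])
    } else {
      list(start = round(sim_cfg$chrom_length / 3),
           end = round(2 * sim_cfg$chrom_length / 3))
    }
  }
  if (is.null(perm_seed)) perm_seed <- sim_cfg$seed + 500000L
  test <- permute_and_test(wt, focal, cfg, seed = perm_seed, n_perm = n_perm)
  list(sim = sim, windows = win, trees = trees, weights = wt, test = test)
}
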
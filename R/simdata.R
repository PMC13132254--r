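#' Simulation configuration for multispecies phased haplotypes
#'
#' Describes a two-species, two-subspecies-per-species sampling design
#' (populations A1, A2, B1, B2 on the species tree ((A1,A2),(B1,B2))), a
#' chromosome cut into non-recombining segments, and an optional introgressed
#' tract at a focal "color locus" where a fraction of A1 haplotypes carry a
#' recent B1-derived haplotype together with a causal SNP that determines a
#' binary wing phenotype.
#'
#' Times are in coalescent units of 2N generations; `theta_within` is the
#' per-bp scaled mutation rate (4Nu), so expected within-population pairwise
#' diversity per bp equals `theta_within`.
#'
#' @param seed integer RNG seed.
#' @param n_diploids_per_subspecies diploid samples per subspecies.
#' @param chrom_length chromosome length in bp.
#' @param segment_bp length of non-recombining segments (one genealogy each).
#' @param split_time_subspecies,split_time_species population split times,
#'   `0 < split_time_subspecies < split_time_species`.
#' @param theta_within per-bp scaled mutation rate.
#' @param tract optional `c(start, end)` 0-based half-open bp interval of the
#'   introgressed color locus.
#' @param introgression_time time of the donor-to-recipient pulse (B1 into
#'   A1), must be below `split_time_species`.
#' @param introgression_fraction probability that an A1 haplotype carries the
#'   introgressed tract.
#' @param causal_pos 1-based bp position of the causal SNP; must lie inside
#'   `tract` when the tract is set.
#' @param dominance `"recessive"` (phenotype 1 iff homozygous for the
#'   introgressed allele) or `"dominant"`.
#' @param n_species,n_subspecies_per_species fixed at 2 in this release;
#'   included so configurations are explicit about the quartet design.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_diploids_per_subspecies = 2L,
                       chrom_length = 1000000L,
                       segment_bp = 5000L,
                       split_time_subspecies = 1.0,
                       split_time_species = 2.0,
                       theta_within = 0.006,
                       tract = NULL,
                       introgression_time = 0.01,
                       introgression_fraction = 0,
                       causal_pos = NULL,
                       dominance = c("recessive", "dominant"),
                       n_species = 2L,
                       n_subspecies_per_species = 2L) {
  dominance <- match.arg(dominance)
  if (n_species != 2L || n_subspecies_per_species != 2L) {
    stop("this release implements the 2-species x 2-subspecies quartet design")
  }
  stopifnot(split_time_subspecies > 0,
            split_time_subspecies < split_time_species,
            theta_within >= 0, chrom_length > 0, segment_bp > 0,
            n_diploids_per_subspecies >= 1,
            introgression_fraction >= 0, introgression_fraction <= 1)
  if (!is.null(tract)) {
    stopifnot(length(tract) == 2, tract[1] >= 0, tract[2] <= chrom_length,
              tract[1] < tract[2])
    if (is.null(causal_pos)) stop("tract set without causal_pos")
    if (causal_pos <= tract[1] || causal_pos > tract[2]) {
      stop("causal_pos must lie inside tract")
    }
    if (introgression_time >= split_time_species) {
      stop("introgression_time must be below split_time_species")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_diploids_per_subspecies = as.integer(n_diploids_per_subspecies),
                 chrom_length = as.integer(chrom_length),
                 segment_bp = as.integer(segment_bp),
                 split_time_subspecies = split_time_subspecies,
                 split_time_species = split_time_species,
                 theta_within = theta_within,
                 tract = if (is.null(tract)) NULL else as.integer(tract),
                 introgression_time = introgression_time,
                 introgression_fraction = introgression_fraction,
                 causal_pos = if (is.null(causal_pos)) NULL else as.integer(causal_pos),
                 dominance = dominance),
            class = "sim_config")
}

## Structured Kingman coalescent for one non-recombining segment.
## pop: integer deme label per lineage (1=A1, 2=A2, 3=B1, 4=B2, 5=A1i carriers).
## Events (backward in time): t_intro A1i -> B1; t_sub A2->A1, B2->B1;
## t_sp B1 -> A1 (root). Returns branches: list of (leafset, length), one per
## child edge of every coalescence, for dropping mutations.
segment_genealogy <- function(pop, t_intro, t_sub, t_sp) {
  n <- length(pop)
  leafsets <- as.list(seq_len(n))
  ctime <- numeric(n)              # time of the node rooting each lineage
  branches <- vector("list", 2 * (n - 1))
  lens <- numeric(2 * (n - 1))
  nb <- 0L
  mtimes <- numeric(0)
  t <- 0
  events <- rbind(c(t_intro, 1), c(t_sub, 2), c(t_sp, 3))
  events <- events[order(events[, 1]), , drop = FALSE]
  ev_i <- 1L
  active <- seq_len(n)
  repeat {
    k_by_pop <- tabulate(pop[active], nbins = 5L)
    rates <- k_by_pop * (k_by_pop - 1) / 2
    total <- sum(rates)
    t_next_ev <- if (ev_i <= nrow(events)) events[ev_i, 1] else Inf
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    if (t + dt < t_next_ev) {
      t <- t + dt
      d <- sample.int(5L, 1L, prob = rates / total)
      idx <- active[pop[active] == d]
      pair <- if (length(idx) == 2) idx else sample(idx, 2)
      for (ch in pair) {
        nb <- nb + 1L
        branches[[nb]] <- leafsets[[ch]]
        lens[nb] <- t - ctime[ch]
      }
      mtimes <- c(mtimes, t)
      leafsets[[pair[1]]] <- c(leafsets[[pair[1]]], leafsets[[pair[2]]])
      ctime[pair[1]] <- t
      active <- active[active != pair[2]]
      if (length(active) == 1L) break
    } else {
      t <- t_next_ev
      type <- events[ev_i, 2]
      ev_i <- ev_i + 1L
      if (type == 1) pop[pop == 5L] <- 3L           # carriers join B1
      if (type == 2) { pop[pop == 2L] <- 1L; pop[pop == 4L] <- 3L }
      if (type == 3) pop[pop == 3L] <- 1L
    }
  }
  list(branches = branches[seq_len(nb)], lens = lens[seq_len(nb)],
       times = mtimes)
}

## Poisson mutations on the branches of a segment genealogy; returns the list
## of derived-carrier leafsets, one entry per mutation (infinite sites).
segment_mutations <- function(gen, mu_per_time) {
  if (mu_per_time <= 0) return(list())
  counts <- stats::rpois(length(gen$lens), mu_per_time * gen$lens)
  rep(gen$branches, counts)
}

#' Simulate phased multispecies haplotypes with an optional introgressed tract
#'
#' Draws one Kingman genealogy per non-recombining segment under the
#' structured coalescent on ((A1,A2),(B1,B2)) and drops infinite-sites
#' mutations with uniform positions. If a tract is configured, each A1
#' haplotype independently carries the introgressed background with
#' probability `introgression_fraction` (drawn once per simulation, so the
#' same haplotypes carry every tract segment); carrier lineages coalesce
#' among themselves until `introgression_time` and then join B1. A causal
#' site is planted at `causal_pos`: carriers and all B1 haplotypes hold the
#' derived allele, and each diploid's phenotype follows the configured
#' dominance (recessive: phenotype 1 iff homozygous derived).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `hap` (a [hap_matrix()]), `samples`
#'   (a [sample_table()]), and `carriers` (logical per A1 haplotype).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nd <- cfg$n_diploids_per_subspecies
  subspp <- c("A1", "A2", "B1", "B2")
  sample_ids <- unlist(lapply(subspp, function(s)
    sprintf("%s_%02d", s, seq_len(nd))))
  hap_sample <- rep(sample_ids, each = 2)
  hap_ss <- rep(rep(subspp, each = nd), each = 2)
  n_hap <- length(hap_sample)
  pop0 <- match(hap_ss, subspp)  # 1..4

  has_tract <- !is.null(cfg$tract)
  carriers <- logical(sum(hap_ss == "A1"))
  if (has_tract && cfg$introgression_fraction > 0) {
    carriers <- stats::runif(length(carriers)) < cfg$introgression_fraction
  }

  seg_starts <- seq(0L, cfg$chrom_length - 1L, by = cfg$segment_bp)
  mu_per_time <- cfg$theta_within / 2 * cfg$segment_bp

  pos_all <- integer(0)
  rows <- list()
  for (s0 in seg_starts) {
    s1 <- min(s0 + cfg$segment_bp, cfg$chrom_length)
    pop <- pop0
    in_tract <- has_tract && s0 < cfg$tract[2] && s1 > cfg$tract[1]
    if (in_tract && any(carriers)) {
      a1_cols <- which(hap_ss == "A1")
      pop[a1_cols[carriers]] <- 5L
    }
    gen <- segment_genealogy(pop, cfg$introgression_time,
                             cfg$split_time_subspecies,
                             cfg$split_time_species)
    muts <- segment_mutations(gen, mu_per_time * (s1 - s0) / cfg$segment_bp)
    if (length(muts) == 0) next
    p <- sort(sample.int(s1 - s0, min(length(muts), s1 - s0)))
    muts <- muts[sample.int(length(muts), length(p))]  # random branch per position
    m <- matrix(0L, length(muts), n_hap)
    m[cbind(rep(seq_along(muts), lengths(muts)), unlist(muts))] <- 1L
    rows[[length(rows) + 1L]] <- m
    pos_all <- c(pos_all, s0 + p)        # 1-based positions in [s0+1, s1]
  }

  if (length(rows) == 0) {
    alleles <- matrix(integer(0), 0, n_hap)
    pos <- integer(0)
  } else {
    alleles <- do.call(rbind, rows)
    pos <- pos_all
  }

  ## plant the causal site
  if (has_tract) {
    row <- integer(n_hap)
    a1_cols <- which(hap_ss == "A1")
    row[a1_cols[carriers]] <- 1L
    row[hap_ss == "B1"] <- 1L
    keep <- pos != cfg$causal_pos
    alleles <- rbind(alleles[keep, , drop = FALSE], row)
    pos <- c(pos[keep], cfg$causal_pos)
    o <- order(pos)
    alleles <- alleles[o, , drop = FALSE]
    pos <- pos[o]
  }

  ## phenotype from causal genotype
  phen <- rep(NA_real_, length(sample_ids))
  if (has_tract) {
    causal_row <- alleles[match(cfg$causal_pos, pos), ]
    dose <- causal_row[seq(1, n_hap, 2)] + causal_row[seq(2, n_hap, 2)]
    phen <- if (cfg$dominance == "recessive") as.numeric(dose == 2)
            else as.numeric(dose >= 1)
  }

  st <- sample_table(sample_ids,
                     species = substr(rep(subspp, each = nd), 1, 1),
                     subspecies = rep(subspp, each = nd),
                     locality = "sim", phenotype = phen)
  hm <- hap_matrix("chr1", pos, alleles, hap_sample)
  list(hap = hm, samples = st, carriers = carriers)
}

#' Configuration for 4-population allele-frequency simulation
#'
#' Balding-Nichols drift model: ancestral frequencies are uniform on
#' (0.05, 0.95) and each population's frequency is a Beta draw centred on the
#' ancestral value with drift parameter `F_drift`. An optional admixture edge
#' mixes a donor population's frequencies into a recipient.
#'
#' @param seed integer RNG seed.
#' @param n_sites number of sites.
#' @param F_drift drift parameter in (0,1), recycled over 4 populations.
#' @param admix_edge optional `list(donor=, recipient=, m=)` with
#'   `m` in \[0,1\].
#' @param site_spacing_bp distance between consecutive sites (for jackknife
#'   blocks).
#' @return list of class `freq_sim_config`.
#' @export
freq_sim_config <- function(seed = 1L, n_sites = 20000L, F_drift = 0.1,
                            admix_edge = NULL, site_spacing_bp = 1000L) {
  F_drift <- rep_len(F_drift, 4)
  if (any(F_drift <= 0 | F_drift >= 1)) stop("F_drift must be in (0,1)")
  if (!is.null(admix_edge)) {
    stopifnot(is.list(admix_edge),
              all(c("donor", "recipient", "m") %in% names(admix_edge)),
              admix_edge$m >= 0, admix_edge$m <= 1)
  }
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 F_drift = F_drift, admix_edge = admix_edge,
                 site_spacing_bp = as.integer(site_spacing_bp)),
            class = "freq_sim_config")
}

#' Simulate a 4-population allele-frequency table
#'
#' @param cfg a [freq_sim_config()].
#' @return a [freq_table()] with populations `pop1..pop4`.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "freq_sim_config"))
  set.seed(cfg$seed + 1000L)  # offset: separate stream from haplotype module
  n <- cfg$n_sites
  p0 <- stats::runif(n, 0.05, 0.95)
  p <- sapply(1:4, function(k) {
    F <- cfg$F_drift[k]
    stats::rbeta(n, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  })
  colnames(p) <- paste0("pop", 1:4)
  if (!is.null(cfg$admix_edge)) {
    d <- cfg$admix_edge$donor; r <- cfg$admix_edge$recipient
    m <- cfg$admix_edge$m
    p[, r] <- (1 - m) * p[, r] + m * p[, d]
  }
  freq_table(chrom = "chr1",
             pos = seq_len(n) * cfg$site_spacing_bp,
             p = p, n_called = matrix(Inf, n, 4,
                                      dimnames = list(NULL, colnames(p))))
}

#' Write a simulated dataset as a reusable fixture
#'
#' Emits a phased plain-text VCF, a metadata TSV (sample, species, subspecies,
#' locality, phenotype) and a flat `key=value` config stub describing the
#' simulation, so the full pipeline can be re-run from files.
#'
#' @param hm a [hap_matrix()].
#' @param st a [sample_table()].
#' @param dir output directory (created if needed).
#' @param cfg optional [sim_config()] echoed into the config stub.
#' @return named character vector of file paths.
#' @export
write_fixture <- function(hm, st, dir, cfg = NULL) {
  stopifnot(inherits(hm, "hap_matrix"), inherits(st, "sample_table"))
  if (length(unique(hm$hap_sample)) == 0) stop("refusing to write 0 samples")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(dir, "haplotypes.vcf")
  tsv <- file.path(dir, "samples.tsv")
  conf <- file.path(dir, "config.txt")
  write_vcf(hm, vcf)
  utils::write.table(st, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c("chrom=chr1")
  if (!is.null(cfg)) {
    flat <- cfg[!vapply(cfg, is.null, logical(1))]
    lines <- c(lines, paste0(names(flat), "=",
                             vapply(flat, function(x) paste(x, collapse = ","),
                                    character(1))))
  }
  writeLines(lines, conf)
  c(vcf = vcf, samples = tsv, config = conf)
}
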
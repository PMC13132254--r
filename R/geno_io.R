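#' Analysis configuration
#'
#' Bundle of the numeric thresholds used across the pipeline. Defaults follow
#' the study design this package implements: GWA site filters of minor allele
#' frequency >= 10% (inclusive) and missingness < 25% (exclusive), 100-SNP
#' genealogy windows, an introgression-topology weight threshold of 0.95
#' (the "intro95" statistic counts windows at or above it), 100-kb shuffle
#' blocks with 50,000 permutations, 500-kb jackknife blocks for f4, 50-kb
#' nucleotide-diversity windows, and the trans-species polymorphism rules
#' (>= 4 polymorphic species when more than three are present; every allele
#' represented by >= 6 copies across species).
#'
#' @param maf_min minimum minor allele frequency, computed on called genotypes.
#' @param missingness_max maximum tolerated missing fraction (strict `<`).
#' @param window_snps SNPs per nonoverlapping genealogy window.
#' @param weight_threshold introgression-topology weight defining intro95.
#' @param perm_block_bp block size (bp) for the permutation null.
#' @param n_perm number of block permutations.
#' @param jackknife_block_bp block size (bp) for the f4 block jackknife.
#' @param pi_window_bp window size (bp) for pooled nucleotide diversity.
#' @param transpoly_min_poly_species minimum polymorphic species (rule i).
#' @param transpoly_min_allele_copies minimum copies per allele (rule iii).
#' @param alpha significance level.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(maf_min = 0.10,
                            missingness_max = 0.25,
                            window_snps = 100L,
                            weight_threshold = 0.95,
                            perm_block_bp = 100000L,
                            n_perm = 50000L,
                            jackknife_block_bp = 500000L,
                            pi_window_bp = 50000L,
                            transpoly_min_poly_species = 4L,
                            transpoly_min_allele_copies = 6L,
                            alpha = 0.05) {
  stopifnot(maf_min > 0, maf_min < 0.5, missingness_max > 0,
            window_snps >= 1, weight_threshold > 0, weight_threshold <= 1,
            perm_block_bp > 0, n_perm >= 1, jackknife_block_bp > 0,
            pi_window_bp > 0, transpoly_min_poly_species >= 1,
            transpoly_min_allele_copies >= 1, alpha > 0, alpha < 1)
  structure(list(
    maf_min = maf_min, missingness_max = missingness_max,
    window_snps = as.integer(window_snps),
    weight_threshold = weight_threshold,
    perm_block_bp = as.integer(perm_block_bp), n_perm = as.integer(n_perm),
    jackknife_block_bp = as.integer(jackknife_block_bp),
    pi_window_bp = as.integer(pi_window_bp),
    transpoly_min_poly_species = as.integer(transpoly_min_poly_species),
    transpoly_min_allele_copies = as.integer(transpoly_min_allele_copies),
    alpha = alpha
  ), class = "analysis_config")
}

#' Sample metadata table
#'
#' @param sample character vector of unique sample ids.
#' @param species,subspecies,locality character vectors, recycled to length.
#' @param phenotype numeric phenotype code in \{0, 0.5, 1\} or `NA`.
#' @return data.frame of class `sample_table` with columns
#'   sample, species, subspecies, locality, phenotype.
#' @export
sample_table <- function(sample, species, subspecies,
                         locality = "loc1", phenotype = NA_real_) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("sample ids must be unique")
  ok <- is.na(phenotype) | phenotype %in% c(0, 0.5, 1)
  if (!all(ok)) stop("phenotype codes must be 0, 0.5, 1 or NA")
  st <- data.frame(sample = sample,
                   species = rep_len(as.character(species), length(sample)),
                   subspecies = rep_len(as.character(subspecies), length(sample)),
                   locality = rep_len(as.character(locality), length(sample)),
                   phenotype = rep_len(as.numeric(phenotype), length(sample)),
                   stringsAsFactors = FALSE)
  class(st) <- c("sample_table", "data.frame")
  st
}

#' Construct a haplotype matrix
#'
#' Sites x haplotypes integer allele codes (0 = REF, 1.. = ALT alleles,
#' `NA` = missing), with 1-based strictly increasing positions. Each diploid
#' sample owns exactly two haplotype columns.
#'
#' @param chrom chromosome name (single string).
#' @param pos integer positions, 1-based, strictly increasing.
#' @param alleles integer matrix, sites x haplotypes.
#' @param hap_sample sample id for each haplotype column.
#' @param ref,alt allele strings per site (`alt` may be comma-separated for
#'   multiallelic records).
#' @return object of class `hap_matrix`.
#' @export
hap_matrix <- function(chrom, pos, alleles, hap_sample,
                       ref = NULL, alt = NULL) {
  pos <- as.integer(pos)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(pos) != nrow(alleles)) stop("pos length != allele rows")
  if (length(pos) > 1 && any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (length(hap_sample) != ncol(alleles)) stop("hap_sample length != haplotype columns")
  tab <- table(hap_sample)
  if (any(tab != 2L)) stop("every sample must contribute exactly 2 haplotypes")
  if (is.null(ref)) ref <- rep("A", length(pos))
  if (is.null(alt)) alt <- rep("T", length(pos))
  hap_id <- paste0(hap_sample, "_h", stats::ave(seq_along(hap_sample), hap_sample,
                                                FUN = seq_along))
  colnames(alleles) <- hap_id
  structure(list(chrom = as.character(chrom)[1], pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 alleles = alleles, hap_sample = as.character(hap_sample),
                 hap_id = hap_id),
            class = "hap_matrix")
}

#' Construct a genotype matrix
#'
#' Sites x samples alternate-allele dosage (0/1/2, `NA` missing), biallelic.
#'
#' @inheritParams hap_matrix
#' @param geno integer matrix sites x samples with values in \{0,1,2,NA\}.
#' @param samples sample ids (column names).
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(chrom, pos, geno, samples, ref = NULL, alt = NULL) {
  pos <- as.integer(pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (length(pos) != nrow(geno)) stop("pos length != genotype rows")
  if (length(pos) > 1 && any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (!all(geno %in% c(0L, 1L, 2L, NA), na.rm = FALSE)) {
    if (!all(is.na(geno) | geno %in% 0:2)) stop("genotype dosages must be 0, 1, 2 or NA")
  }
  if (length(samples) != ncol(geno)) stop("samples length != genotype columns")
  colnames(geno) <- samples
  if (is.null(ref)) ref <- rep("A", length(pos))
  if (is.null(alt)) alt <- rep("T", length(pos))
  structure(list(chrom = as.character(chrom)[1], pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, samples = as.character(samples)),
            class = "geno_matrix")
}

#' Collapse phased haplotypes to genotype dosages
#'
#' Sums the two haplotype alleles per sample; any missing haplotype makes the
#' genotype missing. Multiallelic codes are collapsed to presence of any
#' non-reference allele per haplotype (dosage counts non-reference copies),
#' so statistics modules should normally receive biallelic input.
#'
#' @param hm a [hap_matrix()].
#' @return a [geno_matrix()].
#' @export
as_genotypes <- function(hm) {
  stopifnot(inherits(hm, "hap_matrix"))
  samples <- unique(hm$hap_sample)
  a <- hm$alleles
  a[!is.na(a) & a > 1L] <- 1L
  g <- sapply(samples, function(s) {
    cols <- which(hm$hap_sample == s)
    rowSums(a[, cols, drop = FALSE])
  })
  g <- matrix(as.integer(g), nrow = nrow(a),
              dimnames = list(NULL, samples))
  geno_matrix(hm$chrom, hm$pos, g, samples, hm$ref, hm$alt)
}

#' Read a VCF into the internal genotype or haplotype representation
#'
#' Biallelic mode drops multiallelic records (the dialect every statistic in
#' this package consumes); multiallelic mode keeps them with integer allele
#' codes and is intended for the genealogy-window stage only. Phased mode
#' requires `|` genotype separators and refuses `/` records unless
#' `allow_unphased` is set, signalling that upstream phasing was skipped.
#'
#' @param path VCF file (plain text or gzip).
#' @param mode `"biallelic"` or `"multiallelic"`.
#' @param phased if `TRUE`, return a [hap_matrix()]; else a [geno_matrix()].
#' @param allow_unphased tolerate `/` separators in phased mode.
#' @return [hap_matrix()] or [geno_matrix()].
#' @export
read_vcf <- function(path, mode = c("biallelic", "multiallelic"),
                     phased = FALSE, allow_unphased = FALSE) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  if (length(unique(chrom)) > 1) stop("read_vcf expects a single chromosome")
  if (length(pos) > 1 && any(diff(pos) <= 0)) stop("VCF positions are not strictly increasing")
  gt <- v@gt[, -1, drop = FALSE]
  samples <- colnames(gt)
  ## strip any FORMAT fields beyond GT
  gt <- sub(":.*$", "", gt)
  multi <- grepl(",", alt)
  if (mode == "biallelic" && any(multi)) {
    keep <- !multi
    pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
    gt <- gt[keep, , drop = FALSE]
  }
  if (length(pos) == 0) stop("no records retained from ", path)
  if (phased) {
    has_slash <- grepl("/", gt, fixed = TRUE) & gt != "./."
    if (any(has_slash) && !allow_unphased) {
      stop("unphased genotypes found but phased haplotypes requested")
    }
    sep <- "[|/]"
    a1 <- sub(paste0(sep, ".*$"), "", gt)
    a2 <- sub(paste0("^[^|/]*", sep), "", gt)
    code <- function(x) {
      out <- suppressWarnings(as.integer(x))
      out  # "." -> NA
    }
    n_site <- length(pos)
    alleles <- matrix(NA_integer_, n_site, 2 * length(samples))
    hap_sample <- rep(samples, each = 2)
    alleles[, seq(1, ncol(alleles), 2)] <- code(a1)
    alleles[, seq(2, ncol(alleles), 2)] <- code(a2)
    hap_matrix(chrom[1], pos, alleles, hap_sample, ref, alt)
  } else {
    a1 <- suppressWarnings(as.integer(sub("[|/].*$", "", gt)))
    a2 <- suppressWarnings(as.integer(sub("^[^|/]*[|/]", "", gt)))
    a1[!is.na(a1) & a1 > 1L] <- 1L
    a2[!is.na(a2) & a2 > 1L] <- 1L
    g <- matrix(a1 + a2, length(pos), length(samples),
                dimnames = list(NULL, samples))
    geno_matrix(chrom[1], pos, g, samples, ref, alt)
  }
}

#' Write a haplotype matrix as a phased VCF 4.2 file
#'
#' Plain-text output with `|`-separated GT fields; byte-stable for a given
#' input so fixtures are reproducible.
#'
#' @param hm a [hap_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hm, path) {
  stopifnot(inherits(hm, "hap_matrix"))
  samples <- unique(hm$hap_sample)
  if (length(samples) == 0) stop("refusing to write a VCF with 0 samples")
  i1 <- match(samples, hm$hap_sample)            # first haplotype column
  i2 <- length(hm$hap_sample) - match(samples, rev(hm$hap_sample)) + 1L
  a <- hm$alleles
  chr <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt_cols <- lapply(seq_along(samples), function(k) {
    paste0(chr(a[, i1[k]]), "|", chr(a[, i2[k]]))
  })
  body <- do.call(paste, c(list(hm$chrom, hm$pos, ".", hm$ref, hm$alt,
                                ".", "PASS", ".", "GT"),
                           gt_cols, sep = "\t"))
  header <- c("##fileformat=VCFv4.2",
              "##source=introtopo",
              paste0("##contig=<ID=", hm$chrom, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Infer per-site ancestral alleles from an outgroup with a genus-wide fallback
#'
#' The ancestral allele is the major allele among outgroup calls; at sites
#' where no outgroup call exists it falls back to the most frequent allele
#' across the fallback samples (the whole genus, in the intended use). Ties
#' resolve to the reference allele. Sites with no calls anywhere are `NA`.
#'
#' @param gm a [geno_matrix()].
#' @param outgroup_samples,fallback_samples character vectors of sample ids.
#' @return data.frame with columns `ancestral` (0 = ref, 1 = alt, NA),
#'   `rule` (`"outgroup"`, `"fallback"` or `"none"`).
#' @export
assign_ancestral <- function(gm, outgroup_samples, fallback_samples) {
  stopifnot(inherits(gm, "geno_matrix"), length(outgroup_samples) > 0)
  counts <- function(cols) {
    g <- gm$geno[, cols, drop = FALSE]
    called <- 2 * rowSums(!is.na(g))
    altc <- rowSums(g, na.rm = TRUE)
    list(called = called, alt = altc, ref = called - altc)
  }
  og <- counts(match(outgroup_samples, gm$samples))
  fb <- counts(match(fallback_samples, gm$samples))
  major <- function(cn) ifelse(cn$alt > cn$ref, 1L, 0L)  # tie -> ref
  anc <- ifelse(og$called > 0, major(og),
                ifelse(fb$called > 0, major(fb), NA_integer_))
  rule <- ifelse(og$called > 0, "outgroup",
                 ifelse(fb$called > 0, "fallback", "none"))
  data.frame(ancestral = as.integer(anc), rule = rule,
             stringsAsFactors = FALSE)
}

#' Filter sites on minor allele frequency and missingness
#'
#' Keeps sites with MAF >= `maf_min` (computed on called genotypes; boundary
#' inclusive) and missing fraction strictly below `missingness_max`.
#'
#' @param gm a [geno_matrix()].
#' @param cfg an [analysis_config()].
#' @return filtered [geno_matrix()] with attribute `n_retained`.
#' @export
filter_sites <- function(gm, cfg = analysis_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$geno
  n <- ncol(g)
  n_called <- rowSums(!is.na(g))
  miss_frac <- (n - n_called) / n
  af <- rowSums(g, na.rm = TRUE) / (2 * n_called)
  af[n_called == 0] <- NA_real_
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= cfg$maf_min & miss_frac < cfg$missingness_max
  if (!any(keep)) warning("no sites retained after MAF/missingness filter")
  out <- geno_matrix(gm$chrom, gm$pos[keep], g[keep, , drop = FALSE],
                     gm$samples, gm$ref[keep], gm$alt[keep])
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Subset a haplotype matrix to a set of site indices
#' @param hm a [hap_matrix()].
#' @param idx integer site indices (increasing).
#' @return [hap_matrix()].
#' @export
subset_sites <- function(hm, idx) {
  hap_matrix(hm$chrom, hm$pos[idx], hm$alleles[idx, , drop = FALSE],
             hm$hap_sample, hm$ref[idx], hm$alt[idx])
}
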
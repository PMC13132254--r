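#' Quartet specification for topology weighting
#'
#' Four disjoint haplotype groups with fixed roles: `g1` = sspA1, `g2` =
#' sspA2, `g3` = sspB1, `g4` = sspB2. The species topology is `g1g2|g3g4`;
#' the introgression-compatible topology, declared before any data are seen,
#' is `g1g3|g2g4` (co-mimetic subspecies of the two species clustering);
#' `g1g4|g2g3` is the third arrangement.
#'
#' @param g1,g2,g3,g4 character vectors of haplotype labels.
#' @return list of class `quartet_spec`.
#' @export
quartet_spec <- function(g1, g2, g3, g4) {
  gs <- list(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
  if (any(lengths(gs) == 0)) stop("all four groups must be nonempty")
  all_ids <- unlist(gs)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  structure(gs, class = "quartet_spec")
}

## Topological (unit-branch-length) distances between the leaves of a tree.
## In a binary tree the three quartet pair-sums differ by at least 2 for any
## four distinct leaves, so the argmin identifies the induced split exactly
## even when stored branch lengths are zero.
leaf_topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(t2)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Induced quartet topology for four leaves of a tree
#'
#' Returns which of the three possible splits of `{a,b},{c,d}` the stored
#' (binary) tree induces: `"ab|cd"`, `"ac|bd"` or `"ad|bc"`. Invariant to
#' rooting; zero-length internal branches resolve by the stored topology.
#'
#' @param tree a `phylo`.
#' @param a,b,c,d distinct leaf labels.
#' @return one of `"ab|cd"`, `"ac|bd"`, `"ad|bc"`.
#' @export
quartet_topology <- function(tree, a, b, c, d) {
  labs <- c(a, b, c, d)
  if (anyDuplicated(labs)) stop("leaves must be distinct")
  miss <- setdiff(labs, tree$tip.label)
  if (length(miss)) stop("not leaves of the tree: ", paste(miss, collapse = ", "))
  D <- leaf_topo_dist(tree)
  s <- c(`ab|cd` = D[a, b] + D[c, d],
         `ac|bd` = D[a, c] + D[b, d],
         `ad|bc` = D[a, d] + D[b, c])
  names(which.min(s))
}

#' Topology weights of one window tree over a quartet of groups
#'
#' The weight of topology tau is the fraction of tuples (one leaf from each
#' group) whose induced quartet equals tau. Exhaustive enumeration when the
#' tuple count is at most `exhaustive_cap`; otherwise Monte Carlo with
#' `n_draws` with-replacement draws. Weights always sum to 1.
#'
#' @param tree a `phylo` whose leaves include every group member.
#' @param q a [quartet_spec()].
#' @param exhaustive_cap tuple-count bound for exhaustive enumeration.
#' @param n_draws Monte Carlo draws when above the cap.
#' @return named numeric `c(w_species, w_intro, w_third)` with attributes
#'   `method` and `n_tuples`.
#' @export
weight_window <- function(tree, q, exhaustive_cap = 50000L, n_draws = 10000L) {
  stopifnot(inherits(q, "quartet_spec"))
  miss <- setdiff(unlist(q), tree$tip.label)
  if (length(miss)) stop("group members missing from tree: ",
                         paste(miss, collapse = ", "))
  D <- leaf_topo_dist(tree)
  i1 <- match(q$g1, rownames(D)); i2 <- match(q$g2, rownames(D))
  i3 <- match(q$g3, rownames(D)); i4 <- match(q$g4, rownames(D))
  n_tup <- length(i1) * length(i2) * length(i3) * length(i4)
  if (n_tup <= exhaustive_cap) {
    tup <- expand.grid(a = i1, b = i2, c = i3, d = i4, KEEP.OUT.ATTRS = FALSE)
    method <- "exhaustive"
  } else {
    tup <- data.frame(a = sample(i1, n_draws, TRUE),
                      b = sample(i2, n_draws, TRUE),
                      c = sample(i3, n_draws, TRUE),
                      d = sample(i4, n_draws, TRUE))
    method <- "montecarlo"
  }
  s_sp <- D[cbind(tup$a, tup$b)] + D[cbind(tup$c, tup$d)]   # g1g2|g3g4
  s_in <- D[cbind(tup$a, tup$c)] + D[cbind(tup$b, tup$d)]   # g1g3|g2g4
  s_th <- D[cbind(tup$a, tup$d)] + D[cbind(tup$b, tup$c)]   # g1g4|g2g3
  win_sp <- s_sp < s_in & s_sp < s_th
  win_in <- s_in < s_sp & s_in < s_th
  m <- nrow(tup)
  w <- c(w_species = sum(win_sp) / m,
         w_intro = sum(win_in) / m,
         w_third = sum(!win_sp & !win_in) / m)
  attr(w, "method") <- method
  attr(w, "n_tuples") <- m
  w
}

#' Topology-weight track over all windows of a tree track
#'
#' @param track a [window_trees()] result.
#' @param q a [quartet_spec()].
#' @param cfg an [analysis_config()] (supplies the intro95 threshold).
#' @param exhaustive_cap,n_draws passed to [weight_window()].
#' @return data.frame of class `topo_weight_track`: window coordinates plus
#'   `w_species, w_intro, w_third, method, intro95`.
#' @export
weight_track <- function(track, q, cfg = analysis_config(),
                         exhaustive_cap = 50000L, n_draws = 10000L) {
  stopifnot(inherits(track, "window_tree_track"))
  n <- length(track$trees)
  w <- matrix(NA_real_, n, 3)
  method <- character(n)
  for (i in seq_len(n)) {
    wi <- weight_window(track$trees[[i]], q, exhaustive_cap, n_draws)
    w[i, ] <- wi
    method[i] <- attr(wi, "method")
  }
  out <- cbind(track$windows,
               data.frame(w_species = w[, 1], w_intro = w[, 2],
                          w_third = w[, 3], method = method))
  out$intro95 <- out$w_intro >= cfg$weight_threshold
  class(out) <- c("topo_weight_track", "data.frame")
  out
}

#' Count intro95 windows inside a region
#'
#' Number of windows whose bp midpoint lies in `[region$start, region$end)`
#' and whose introgression-topology weight is at least the threshold
#' (boundary inclusive: a weight of exactly 0.95 counts).
#'
#' @param track a [weight_track()] frame.
#' @param region list or one-row data.frame with `start`, `end` (0-based
#'   half-open bp).
#' @param cfg an [analysis_config()].
#' @return integer count.
#' @export
intro95_count <- function(track, region, cfg = analysis_config()) {
  if (region$end <= min(track$start) || region$start >= max(track$end)) {
    warning("region lies outside the track span")
    return(0L)
  }
  inside <- track$mid >= region$start & track$mid < region$end
  sum(inside & track$w_intro >= cfg$weight_threshold)
}

#' Write a topology-weight track as TSV
#' @param track a [weight_track()] frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weight_track <- function(track, path) {
  cols <- c("chrom", "start", "end", "w_species", "w_intro", "w_third",
            "method", "intro95")
  utils::write.table(as.data.frame(track)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
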
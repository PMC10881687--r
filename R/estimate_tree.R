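#' Pairwise-deletion Jukes-Cantor distance matrix
#'
#' Distances use only sites called in both samples (pairwise deletion) with
#' the JC69 correction \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}\hat p)}.
#' Saturated comparisons (\eqn{\hat p \ge 0.70}) are truncated at the
#' distance of p = 0.70 (about 2.03 substitutions/site) so that sparse,
#' noisy overlaps yield large finite distances instead of infinities.
#'
#' @param aln a [haplo_alignment()].
#' @param min_overlap minimum number of co-called sites per pair
#'   (default 50); a pair below the floor raises an error naming it. With
#'   `min_overlap = 0`, a pair sharing no called sites gets the cap
#'   distance — no overlap means no information, so the pair is treated as
#'   maximally diverged rather than rejected.
#' @return a `dist`-compatible symmetric matrix of substitutions/site, with
#'   the per-pair overlap counts attached as attribute `overlap`.
#' @export
jc_pairwise_distances <- function(aln, min_overlap = 50L) {
  m <- aln_mat(aln)
  n <- nrow(m)
  called <- m != "N"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  OV <- matrix(ncol(m), n, n)
  p_cap <- 0.70
  d_cap <- -0.75 * log(1 - 4 * p_cap / 3)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- called[i, ] & called[j, ]
      ov <- sum(both)
      if (ov < max(min_overlap, 1L)) {
        if (min_overlap > 0L) {
          input_error(sprintf(
            "samples %s and %s share only %d called sites (floor %d)",
            rownames(m)[i], rownames(m)[j], ov, min_overlap))
        }
        D[i, j] <- D[j, i] <- d_cap
        OV[i, j] <- OV[j, i] <- ov
        next
      }
      p <- sum(m[i, both] != m[j, both]) / ov
      d <- if (p >= p_cap) d_cap else -0.75 * log(1 - 4 * p / 3)
      D[i, j] <- D[j, i] <- d
      OV[i, j] <- OV[j, i] <- ov
    }
  }
  attr(D, "overlap") <- OV
  D
}

#' Estimate a dated tree from a patchy alignment
#'
#' Desk-scale substitute for joint Bayesian tree inference: JC-corrected
#' pairwise-deletion distances, UPGMA clustering, node heights converted
#' from substitutions/site to years through the clock rate, and tips
#' shifted to their true collection dates. The UPGMA tree is ultrametric
#' with every tip at the most recent date; shifting a tip to an older date
#' can place it older than its UPGMA parent, in which case the parent (and
#' its ancestors as needed) is clamped to the tip's date, producing a
#' deterministic zero-length-branch repair.
#'
#' @param aln a [haplo_alignment()] with >= 3 samples.
#' @param meta a [sample_meta()] covering every alignment sample.
#' @param clock_rate substitutions/site/year used for the time conversion.
#' @param min_overlap pairwise-deletion overlap floor (see
#'   [jc_pairwise_distances()]).
#' @return a [dated_tree()].
#' @export
estimate_tree <- function(aln, meta, clock_rate, min_overlap = 50L) {
  m <- aln_mat(aln)
  if (nrow(m) < 3L) input_error("need at least 3 samples")
  if (clock_rate <= 0) input_error("clock_rate must be positive")
  if (!all(rownames(m) %in% meta$id)) {
    input_error("metadata must cover every alignment sample")
  }
  dates <- stats::setNames(meta$date, meta$id)[rownames(m)]

  D <- jc_pairwise_distances(aln, min_overlap)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)          # ultrametric, heights in subs/site
  phy$edge.length <- phy$edge.length / clock_rate   # years

  # UPGMA node times anchored at the latest collection date, then tips
  # moved to their own dates with upward clamping (post-order minimum)
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  t_latest <- max(dates)
  times <- t_latest - (max(depth) - depth)   # calendar times, UPGMA heights
  times[seq_len(ntip)] <- dates[phy$tip.label]
  po <- rev(seq_len(nrow(phy$edge)))         # cladewise edges reversed
  phy2 <- stats::reorder(phy, "cladewise")
  for (e in rev(seq_len(nrow(phy2$edge)))) {
    par <- phy2$edge[e, 1L]; ch <- phy2$edge[e, 2L]
    if (times[par] > times[ch]) times[par] <- times[ch]
  }
  phy2$edge.length <- times[phy2$edge[, 2L]] - times[phy2$edge[, 1L]]
  dated_tree(phy2, dates)
}
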
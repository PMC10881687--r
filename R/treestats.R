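#' Largest labelled-only monophyletic clade, as a proportion
#'
#' Over all clades of the rooted tree (subtrees, including single tips)
#' whose tip sets contain only labelled tips, returns the size of the
#' largest divided by the number of labelled tips. A value of 1 means the
#' labelled tips are monophyletic; the floor is `1/|labels|`, since a
#' single labelled tip is always a labelled-only clade. Branch lengths and
#' child order are irrelevant. Computed in one post-order pass.
#'
#' @param tree a [dated_tree()] or rooted `phylo`.
#' @param labels character set of focal tip ids (non-empty, all present in
#'   the tree).
#' @return proportion in `(0, 1]`.
#' @export
largest_monophyletic_proportion <- function(tree, labels) {
  phy <- if (inherits(tree, "dated_tree")) tree$phy else tree
  if (!inherits(phy, "phylo")) input_error("tree must be a phylo or dated_tree")
  if (!ape::is.rooted(phy)) input_error("monophyly requires a rooted tree")
  labels <- unique(as.character(labels))
  if (!length(labels)) input_error("label set must be non-empty")
  missing <- setdiff(labels, phy$tip.label)
  if (length(missing)) {
    input_error(paste0("labels not in tree: ", paste(missing, collapse = ", ")))
  }
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  is_lab <- phy$tip.label %in% labels

  # post-order over edges: pure[v] = subtree contains labelled tips only,
  # size[v] = number of tips in subtree
  pure <- c(is_lab, rep(TRUE, phy$Nnode))
  size <- c(rep(1L, ntip), rep(0L, phy$Nnode))
  phy <- stats::reorder(phy, "cladewise")
  for (e in rev(seq_len(nrow(phy$edge)))) {
    par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    pure[par] <- pure[par] && pure[ch]
    size[par] <- size[par] + size[ch]
  }
  best <- max(size[pure][size[pure] > 0L])
  best / length(labels)
}

#' Monophyly-proportion distribution over a tree set
#'
#' Uniformly subsamples `min(n_subsample, length(trees))` trees (without
#' replacement by default; set `replace = TRUE` for strict bootstrap
#' semantics) and evaluates [largest_monophyletic_proportion()] on each —
#' the posterior summary of support for a focal lineage being
#' monophyletic.
#'
#' @param trees a `tree_set` (list of [dated_tree()]s) or `multiPhylo`.
#' @param labels focal tip id set.
#' @param n_subsample number of trees to evaluate (default 1000).
#' @param seed integer seed.
#' @param replace subsample with replacement?
#' @return list of class `monophyly_distribution`: `values` (one per
#'   evaluated tree), `labels`, `n_labeled`, and `summary` (median and
#'   2.5/97.5% quantiles).
#' @export
monophyly_distribution <- function(trees, labels, n_subsample = 1000L,
                                   seed = 1L, replace = FALSE) {
  if (!length(trees)) input_error("tree set must be non-empty")
  set.seed(seed)
  n_take <- if (replace) n_subsample else min(n_subsample, length(trees))
  idx <- sample.int(length(trees), n_take, replace = replace)
  vals <- vapply(idx, function(i) {
    largest_monophyletic_proportion(trees[[i]], labels)
  }, numeric(1))
  structure(list(
    values = vals,
    labels = unique(as.character(labels)),
    n_labeled = length(unique(as.character(labels))),
    summary = stats::quantile(vals, c(0.5, 0.025, 0.975))
  ), class = "monophyly_distribution")
}

#' @rdname monophyly_distribution
#' @param dist a `monophyly_distribution`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_monophyly <- function(dist, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(tree_index = seq_along(dist$values),
                                proportion = dist$values),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      median = unname(dist$summary[1L]),
      q025 = unname(dist$summary[2L]),
      q975 = unname(dist$summary[3L]),
      n_labeled = dist$n_labeled
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(dist)
}
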
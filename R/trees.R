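#' Dated trees
#'
#' A dated tree couples a rooted `ape::phylo` topology (branch lengths in
#' calendar years) with named tip dates in decimal years. Node times run
#' forward in calendar time: a parent node is strictly older (smaller
#' decimal year) than, or equal in degenerate cases to, each child, and
#' every tip sits exactly at its collection date.
#'
#' @param phy a rooted `phylo` with branch lengths in years.
#' @param tip_dates named numeric vector of decimal years, names matching
#'   `phy$tip.label`.
#' @return an object of class `dated_tree`: a list with elements `phy` and
#'   `tip_dates`.
#' @export
dated_tree <- function(phy, tip_dates) {
  if (!inherits(phy, "phylo")) input_error("phy must be an ape phylo object")
  if (is.null(phy$edge.length)) input_error("phy must carry branch lengths")
  if (!ape::is.rooted(phy)) input_error("dated trees must be rooted")
  if (is.null(names(tip_dates)) ||
      !setequal(names(tip_dates), phy$tip.label)) {
    input_error("tip_dates names must match the tree's tip labels")
  }
  tip_dates <- tip_dates[phy$tip.label]
  dt <- structure(list(phy = phy, tip_dates = tip_dates),
                  class = "dated_tree")
  nt <- node_times(dt)
  spread <- diff(range(nt[seq_along(phy$tip.label)] -
                         tip_dates[phy$tip.label]))
  if (spread > 1e-6 * max(1, diff(range(tip_dates)) + 1)) {
    input_error("branch lengths are inconsistent with the tip dates")
  }
  dt
}

#' Node calendar times of a dated tree
#'
#' @param dt a [dated_tree()].
#' @return numeric vector of decimal years indexed like the phylo node
#'   numbering (tips first, then internal nodes).
#' @export
node_times <- function(dt) {
  phy <- dt$phy
  depth <- ape::node.depth.edgelength(phy)  # distance from root, years
  # anchor on the first tip's date
  root_time <- dt$tip_dates[[phy$tip.label[1L]]] - depth[1L]
  root_time + depth
}

#' Root height (age of the root below the most recent tip, in years)
#'
#' @param dt a [dated_tree()].
#' @return non-negative number of years.
#' @export
root_height <- function(dt) {
  nt <- node_times(dt)
  max(dt$tip_dates) - nt[ape::Ntip(dt$phy) + 1L]
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf(
    "dated_tree: %d tips, dates %.1f-%.1f, root height %.1f years\n",
    ape::Ntip(x$phy), min(x$tip_dates), max(x$tip_dates), root_height(x)
  ))
  invisible(x)
}

#' Read / write dated trees as Newick plus a tip-date CSV
#'
#' The Newick file stores branch lengths in years; the companion CSV
#' (columns `id`, `date`) carries the calendar calibration.
#'
#' @param dt a [dated_tree()].
#' @param tree_path,dates_path file paths.
#' @rdname dated_tree_io
#' @export
write_dated_tree <- function(dt, tree_path, dates_path) {
  ape::write.tree(dt$phy, tree_path)
  utils::write.csv(
    data.frame(id = names(dt$tip_dates), date = as.numeric(dt$tip_dates)),
    dates_path, row.names = FALSE, quote = FALSE
  )
  invisible(tree_path)
}

#' @rdname dated_tree_io
#' @export
read_dated_tree <- function(tree_path, dates_path) {
  phy <- ape::read.tree(tree_path)
  d <- utils::read.csv(dates_path, stringsAsFactors = FALSE)
  dated_tree(phy, stats::setNames(d$date, d$id))
}

#' Write a collection of dated trees as a NEXUS tree block
#'
#' @param trees list of [dated_tree()] objects on the same tips.
#' @param path output path.
#' @export
write_tree_set_nexus <- function(trees, path) {
  phys <- lapply(trees, function(t) t$phy)
  class(phys) <- "multiPhylo"
  ape::write.nexus(phys, file = path)
  invisible(path)
}
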
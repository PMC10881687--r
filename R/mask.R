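#' Bycatch masking configuration
#'
#' Controls how patchy missingness is laid onto a complete alignment.
#' Missing positions are placed as contiguous runs with geometric lengths —
#' the run-length structure seen in capture bycatch, where short stretches
#' fail to attract reads — until each sample's realized coverage breadth is
#' within ±0.02 of its target.
#'
#' @param target_coverage a single proportion applied to every sample, a
#'   per-sample numeric vector (recycled by name-free position), or a
#'   function `function(n)` drawing one target per sample (e.g. the
#'   bycatch-like `function(n) runif(n, 0.05, 1)`).
#' @param mean_block_length expected missing-run length in bp (>= 1).
#' @param seed integer seed.
#' @return object of class `mask_config`.
#' @export
mask_config <- function(target_coverage = 0.5, mean_block_length = 300,
                        seed = 1L) {
  if (mean_block_length < 1) input_error("mean_block_length must be >= 1")
  if (is.numeric(target_coverage) &&
      (any(target_coverage < 0) || any(target_coverage > 1))) {
    input_error("target_coverage must lie in [0, 1]")
  }
  structure(list(target_coverage = target_coverage,
                 mean_block_length = mean_block_length,
                 seed = as.integer(seed)),
            class = "mask_config")
}

#' Mask an alignment into patchy bycatch-like data
#'
#' Per sample, geometric-length missing runs (mean `mean_block_length`) are
#' dropped at uniform random start positions until the realized coverage
#' breadth is within ±0.02 of the sample's target; the final run is
#' truncated so the tolerance is always met. Runs wrap around the end of
#' the alignment (the mitogenome is circular), keeping missingness uniform
#' along the genome. Unmasked characters are untouched; masked ones
#' become `N`.
#'
#' @param aln a [haplo_alignment()].
#' @param cfg a [mask_config()].
#' @return a [haplo_alignment()] of the same dimensions.
#' @export
apply_bycatch_mask <- function(aln, cfg) {
  m <- aln_mat(aln)
  n <- nrow(m); L <- ncol(m)
  set.seed(cfg$seed)
  tc <- cfg$target_coverage
  targets <- if (is.function(tc)) tc(n) else rep_len(tc, n)
  if (any(targets < 0) || any(targets > 1)) {
    input_error("target_coverage must lie in [0, 1]")
  }
  p_geom <- 1 / cfg$mean_block_length

  for (i in seq_len(n)) {
    want_missing <- round((1 - targets[i]) * L)
    if (want_missing <= 0) next
    if (want_missing >= L) { m[i, ] <- "N"; next }
    missing <- logical(L)
    tol <- 0.02 * L
    while (want_missing - sum(missing) > tol) {
      len <- min(1L + stats::rgeom(1L, p_geom), L)
      start <- sample.int(L, 1L)
      run <- ((start + seq_len(len) - 2L) %% L) + 1L  # circular mitogenome
      new <- run[!missing[run]]
      room <- want_missing - sum(missing)
      if (length(new) > room) new <- new[seq_len(room)]
      missing[new] <- TRUE
    }
    m[i, missing] <- "N"
  }
  haplo_alignment(m)
}
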
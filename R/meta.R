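#' Sample metadata tables
#'
#' Per-sample metadata: id, collection date in decimal years, prior cluster
#' label (the a-priori grouping handed to the discriminant analysis) and,
#' for synthetic data only, the true deme of origin. Stored as a plain
#' data.frame with columns `id`, `date`, `prior_cluster`, `deme`.
#'
#' @param id character vector of unique sample ids.
#' @param date numeric decimal-year collection dates.
#' @param prior_cluster character labels (two levels expected downstream).
#' @param deme character truth labels; defaults to `prior_cluster`.
#' @return a `data.frame` of class `sample_meta`.
#' @export
sample_meta <- function(id, date, prior_cluster, deme = prior_cluster) {
  id <- as.character(id)
  if (anyDuplicated(id)) input_error("sample ids must be unique")
  if (length(date) != length(id) || length(prior_cluster) != length(id)) {
    input_error("metadata columns must have equal length")
  }
  if (!is.numeric(date) || anyNA(date)) {
    input_error("dates must be numeric decimal years")
  }
  out <- data.frame(
    id = id, date = as.numeric(date),
    prior_cluster = as.character(prior_cluster),
    deme = as.character(deme),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Generate synthetic sample metadata for a two-deme study
#'
#' Draws heterochronous collection dates uniformly over the sampling window
#' for each deme. Prior cluster labels equal the deme of origin, emulating a
#' study where geographic origin supplies the a-priori clustering.
#'
#' @param n_conferta,n_armigera samples per deme.
#' @param sampling_window numeric length-2, earliest and latest decimal year.
#' @param seed integer seed.
#' @return a [sample_meta()] data.frame.
#' @export
synthesize_meta <- function(n_conferta, n_armigera,
                            sampling_window = c(1900, 2020), seed = 1L) {
  if (n_conferta + n_armigera < 2L) input_error("need at least 2 samples")
  if (sampling_window[1] > sampling_window[2]) {
    input_error("sampling window earliest must not exceed latest")
  }
  set.seed(seed)
  n <- n_conferta + n_armigera
  deme <- c(rep("conferta", n_conferta), rep("armigera", n_armigera))
  dates <- stats::runif(n, sampling_window[1], sampling_window[2])
  sample_meta(
    id = sprintf("%s_%03d", substr(deme, 1, 3), seq_len(n)),
    date = round(dates, 3),
    prior_cluster = deme
  )
}

#' @rdname sample_meta
#' @param path CSV path with columns id, date, prior_cluster and optionally
#'   deme.
#' @export
read_meta_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "date", "prior_cluster")
  if (!all(need %in% names(d))) {
    input_error("metadata CSV needs columns id, date, prior_cluster")
  }
  sample_meta(d$id, d$date, d$prior_cluster,
              if ("deme" %in% names(d)) d$deme else d$prior_cluster)
}

#' @rdname sample_meta
#' @param meta a `sample_meta` object.
#' @export
write_meta_csv <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
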
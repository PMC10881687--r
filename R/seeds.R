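#' Derive a reproducible child seed from a root seed and a stage label
#'
#' All stochastic stages of the pipeline draw their seed through this
#' function so that a single root seed fixes every random stream, while
#' distinct stages (and distinct datasets within a stage) get effectively
#' independent streams.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name, e.g. `"mask"`.
#' @param id optional dataset identifier (coerced to character).
#' @return a positive integer below 2^31 - 1, suitable for `set.seed()`.
#' @export
derive_seed <- function(root_seed, stage, id = NULL) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  key <- paste0(stage, if (!is.null(id)) paste0("::", as.character(id)))
  h <- as.numeric(root_seed) %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# internal: stop with a classed input error (all user-input failures share it)
input_error <- function(msg) {
  stop(errorCondition(msg, class = c("bycatchsim_input_error", "error")))
}
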
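#' Haploid alignment objects
#'
#' A haploid alignment is a character matrix over `{A, C, G, T, N}` with one
#' row per sample (rownames are sample ids) and one column per reference
#' position. `N` marks a missing base: a position where no base was called
#' for that sample (absence of data, not an indel). This is the substrate
#' for coverage masking, coverage filtering, DAPC encoding and pairwise
#' distances.
#'
#' @param mat character matrix with rownames; entries in `{A,C,G,T,N}`.
#' @return an object of class `haplo_alignment` (a validated character
#'   matrix).
#' @export
haplo_alignment <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat)) {
    input_error("alignment must be a character matrix")
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) {
    input_error("alignment must have at least one sample and one site")
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    input_error("alignment rows must carry unique sample ids")
  }
  bad <- !(mat %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    input_error("alignment characters must be A, C, G, T or N")
  }
  structure(mat, class = c("haplo_alignment", "matrix", "array"))
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat(sprintf(
    "haplo_alignment: %d samples x %d sites (%.1f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(unclass(x) == "N")
  ))
  invisible(x)
}

# internal: strip class for plain matrix work
aln_mat <- function(aln) {
  m <- unclass(aln)
  attr(m, "class") <- NULL
  m
}

# internal: subset samples, keep class and all columns
aln_subset <- function(aln, keep) {
  m <- aln_mat(aln)[keep, , drop = FALSE]
  haplo_alignment(m)
}

#' Read / write alignments as FASTA
#'
#' FASTA is the interchange format: one record per sample, `N` for missing
#' positions. Reading goes through [ape::read.FASTA()]; any ambiguity code
#' other than A/C/G/T is collapsed to `N`.
#'
#' @param path file path.
#' @rdname fasta_io
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  m[!(m %in% c("A", "C", "G", "T"))] <- "N"
  haplo_alignment(m)
}

#' @param aln a [haplo_alignment()].
#' @rdname fasta_io
#' @export
write_alignment_fasta <- function(aln, path) {
  m <- aln_mat(aln)
  lines <- character(2L * nrow(m))
  lines[seq(1L, by = 2L, length.out = nrow(m))] <- paste0(">", rownames(m))
  lines[seq(2L, by = 2L, length.out = nrow(m))] <-
    apply(m, 1L, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}
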
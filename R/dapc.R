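#' Encode a patchy haploid alignment as a numeric genotype matrix
#'
#' Retains sites polymorphic among called bases. Per site the major allele
#' (most frequent among called bases; ties broken alphabetically) is coded
#' 0 and each non-major allele gets its own 0/1 indicator column, so
#' tri-allelic sites expand to two columns. Missing cells are imputed with
#' the column mean of the observed values — deterministic, and the standard
#' choice for genotype PCA — which is precisely the step through which
#' low coverage pulls samples toward the global centroid.
#'
#' @param aln a [haplo_alignment()] with >= 2 samples.
#' @return list of class `encoded_matrix`: `mat` (samples x columns, fully
#'   numeric), `site` (1-based alignment position per column), `allele`
#'   (the minor allele each column indicates), `imputed` (logical matrix
#'   marking mean-imputed cells).
#' @export
encode_alignment <- function(aln) {
  m <- aln_mat(aln)
  if (nrow(m) < 2L) input_error("need at least 2 samples to encode")
  cols <- list(); sites <- integer(0); alleles <- character(0)
  imput <- list()
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    called <- x != "N"
    if (!any(called)) next                      # all-missing column
    tab <- table(x[called])
    if (length(tab) < 2L) next                  # monomorphic among called
    major <- names(tab)[which.max(tab)]         # which.max: first = ties
    # ties broken alphabetically: table() names are sorted, which.max
    # returns the first maximal entry
    for (a in setdiff(names(tab), major)) {
      v <- as.numeric(x == a)
      v[!called] <- NA
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cols[[length(cols) + 1L]] <- v
      sites <- c(sites, j)
      alleles <- c(alleles, a)
      imput[[length(cols)]] <- !called
    }
  }
  if (!length(cols)) {
    stop(errorCondition("no variation: no polymorphic sites among called bases",
                        class = c("bycatchsim_no_variation", "error")))
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- rownames(m)
  structure(list(
    mat = mat, site = sites, allele = alleles,
    imputed = do.call(cbind, imput)
  ), class = "encoded_matrix")
}

#' PCA reduction of an encoded genotype matrix
#'
#' Columns are centered (not scaled) and the covariance eigendecomposition
#' is taken through an SVD. The number of retained axes is
#' `ceiling(retain_fraction * rank)`, the "first 30% of principal
#' components" rule used to avoid over-fitting the discriminant function.
#'
#' @param enc an [encode_alignment()] result.
#' @param retain_fraction fraction of non-null axes to keep (default 0.30).
#' @return list of class `pca_reduction`: `scores` (n x n_pcs),
#'   `eigenvalues` (all positive eigenvalues, decreasing), `loadings`
#'   (columns x n_pcs), `n_pcs`, `rank`, and the column `center`.
#' @export
pca_reduce <- function(enc, retain_fraction = 0.30) {
  if (retain_fraction <= 0 || retain_fraction > 1) {
    input_error("retain_fraction must be in (0, 1]")
  }
  X <- enc$mat
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  tol <- max(sv$d) * 1e-8
  rank <- sum(sv$d > tol)
  if (rank == 0L) input_error("rank-0 matrix: no variation after centering")
  n_pcs <- max(1L, ceiling(retain_fraction * rank))
  eig <- sv$d[seq_len(rank)]^2 / (nrow(X) - 1L)
  keep <- seq_len(n_pcs)
  structure(list(
    scores = Xc %*% sv$v[, keep, drop = FALSE],
    eigenvalues = eig,
    loadings = sv$v[, keep, drop = FALSE],
    n_pcs = n_pcs, rank = rank, center = ctr
  ), class = "pca_reduction")
}

#' Two-group discriminant analysis on retained principal components
#'
#' Finds the single linear discriminant axis maximizing between-group over
#' within-group variance of the PC scores, projects every sample onto it,
#' and converts projections to membership probabilities with a
#' one-dimensional Gaussian model per group (group means, pooled
#' within-group variance, equal priors). Site loadings are the squared
#' back-projection of the discriminant axis through the PC loadings onto
#' encoded columns, summed per alignment site.
#'
#' @param pca a [pca_reduce()] result.
#' @param prior_clusters character vector, exactly two distinct labels,
#'   each with >= 2 samples, aligned with the score rows.
#' @param enc optional [encode_alignment()] result; when supplied,
#'   per-site loadings are returned.
#' @return list of class `dapc_result`: `n_pcs_retained`, `pc_scores`,
#'   `discriminant_axis` (unit loadings on PCs), `projection` (per-sample
#'   discriminant coordinate), `membership` (n x 2, columns named by
#'   cluster), `assigned` (label of the higher-membership cluster),
#'   `admixed` (logical, via [classify_admixed()]), `site_loadings`.
#' @export
dapc_fit <- function(pca, prior_clusters, enc = NULL) {
  labs <- as.character(prior_clusters)
  lev <- sort(unique(labs))
  if (length(lev) != 2L) input_error("exactly two prior clusters required")
  if (any(table(labs) < 2L)) input_error("each cluster needs >= 2 samples")
  S <- pca$scores
  if (nrow(S) != length(labs)) {
    input_error("prior_clusters must align with score rows")
  }
  g1 <- labs == lev[1L]
  m1 <- colMeans(S[g1, , drop = FALSE])
  m2 <- colMeans(S[!g1, , drop = FALSE])
  W <- (crossprod(sweep(S[g1, , drop = FALSE], 2L, m1)) +
        crossprod(sweep(S[!g1, , drop = FALSE], 2L, m2))) / (nrow(S) - 2L)
  a <- tryCatch(solve(W, m1 - m2), error = function(e) {
    # ridge fallback for a numerically singular pooled scatter
    solve(W + diag(1e-8 * max(diag(W), 1e-12), ncol(W)), m1 - m2)
  })
  a <- a / sqrt(sum(a^2))
  z <- drop(S %*% a)
  mu <- c(mean(z[g1]), mean(z[!g1]))
  s2 <- (sum((z[g1] - mu[1])^2) + sum((z[!g1] - mu[2])^2)) / (nrow(S) - 2L)
  if (s2 <= 0) {
    input_error("zero within-group variance on the discriminant axis; groups are degenerate (identical sequences within each group?)")
  }
  # equal-prior 1-D Gaussian posterior, computed stably in log space
  d1 <- -(z - mu[1])^2 / (2 * s2)
  d2 <- -(z - mu[2])^2 / (2 * s2)
  p1 <- 1 / (1 + exp(d2 - d1))
  membership <- cbind(p1, 1 - p1)
  colnames(membership) <- lev
  rownames(membership) <- rownames(S)
  assigned <- lev[(membership[, 2L] > membership[, 1L]) + 1L]

  site_loadings <- NULL
  if (!is.null(enc)) {
    v <- drop(pca$loadings %*% a)^2      # per encoded column
    site_loadings <- tapply(v, enc$site, sum)
    site_loadings <- data.frame(
      site = as.integer(names(site_loadings)),
      loading = as.numeric(site_loadings)
    )
  }
  structure(list(
    n_pcs_retained = pca$n_pcs,
    pc_scores = S,
    discriminant_axis = a,
    projection = z,
    membership = membership,
    assigned = assigned,
    admixed = classify_admixed(membership),
    site_loadings = site_loadings
  ), class = "dapc_result")
}

#' Classify samples as admixed from membership probabilities
#'
#' A sample is admixed when its assigned-cluster probability falls inside
#' the closed admixture interval `[low, high]` — intermediate assignment
#' probabilities indicate mixed ancestry between the clusters.
#'
#' @param membership n x 2 matrix of membership probabilities.
#' @param low,high interval endpoints, inclusive (defaults 0.01 and 0.99).
#' @return logical vector of admixed flags.
#' @export
classify_admixed <- function(membership, low = 0.01, high = 0.99) {
  if (low >= high) input_error("low must be < high")
  p <- pmax(membership[, 1L], membership[, 2L])
  p >= low & p <= high
}

#' Regression of admixed proportion on dataset composition
#'
#' Per dataset computes x = proportion of samples labelled with the
#' minority cluster and y = proportion of samples flagged admixed, then
#' fits [linear_fit()] — the summary used to show that admixture signal
#' scales with dataset composition.
#'
#' @param results list (>= 3 datasets) of lists with elements `admixed`
#'   (logical) and `labels` (prior cluster labels).
#' @return a `regression_result` with the per-dataset points attached as
#'   attribute `points`.
#' @export
admixture_vs_composition <- function(results) {
  if (length(results) < 3L) input_error("need at least 3 datasets")
  pts <- t(vapply(results, function(r) {
    tab <- table(r$labels)
    minority <- min(tab) / sum(tab)
    c(x = as.numeric(minority), y = mean(r$admixed))
  }, numeric(2)))
  fit <- linear_fit(pts[, "x"], pts[, "y"])
  attr(fit, "points") <- as.data.frame(pts)
  fit
}
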
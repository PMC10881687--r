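test_that("alignment encoding keeps polymorphic sites and mean-imputes", {
  # site 1: A x6 / G x4 -> one indicator column with four 1s
  # site 2: monomorphic -> dropped; site 3: all missing -> dropped
  # site 4: A/G with one missing among 9 called (3 G) -> imputed 3/9
  s1 <- c(rep("A", 6), rep("G", 4))
  s2 <- rep("C", 10)
  s3 <- rep("N", 10)
  s4 <- c(rep("A", 6), rep("G", 3), "N")
  m <- cbind(s1, s2, s3, s4)
  rownames(m) <- paste0("x", 1:10)
  colnames(m) <- NULL
  enc <- encode_alignment(haplo_alignment(m))
  expect_equal(enc$site, c(1L, 4L))
  expect_equal(sum(enc$mat[, 1]), 4)
  expect_equal(unname(enc$mat[10, 2]), 3 / 9)
  expect_true(enc$imputed[10, 2])
  expect_false(any(is.na(enc$mat)))
})

test_that("tri-allelic sites expand to one indicator per non-major allele", {
  s <- c(rep("A", 5), rep("G", 3), rep("T", 2))
  m <- cbind(s, c(rep("A", 9), "C"))
  rownames(m) <- paste0("x", 1:10)
  colnames(m) <- NULL
  enc <- encode_alignment(haplo_alignment(m))
  expect_equal(enc$site, c(1L, 1L, 2L))
  expect_setequal(enc$allele[enc$site == 1L], c("G", "T"))
})

test_that("encoding a monomorphic alignment raises a no-variation error", {
  aln <- aln_from_strings(c("AAAA", "AAAA", "AANA"))
  expect_error(encode_alignment(aln), class = "bycatchsim_no_variation")
})

test_that("PCA reduction reproduces the covariance eigenstructure", {
  d <- make_two_deme_data(12, L = 1500, seed = 31)
  enc <- encode_alignment(d$aln)
  pca <- pca_reduce(enc, retain_fraction = 1.0)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  # score-column variances equal the eigenvalues (eigendecomposition oracle)
  ev <- eigen(stats::cov(enc$mat), symmetric = TRUE, only.values = TRUE)$values
  vars <- apply(pca$scores, 2, stats::var)
  expect_equal(vars, ev[seq_along(vars)], tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank scores preserve centered distances
  expect_equal(as.matrix(stats::dist(pca$scores)),
               as.matrix(stats::dist(scale(enc$mat, scale = FALSE))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # 30% rule keeps ceiling(0.3 * rank) axes
  p30 <- pca_reduce(enc, 0.30)
  expect_equal(p30$n_pcs, ceiling(0.3 * p30$rank))
})

test_that("membership probabilities follow the 1-D Gaussian model", {
  # fabricated scores: two tight groups 12 pooled-sd apart on axis 1
  set.seed(9)
  z <- c(rnorm(20, 0, 1), rnorm(20, 12, 1))
  scores <- cbind(z, rnorm(40, 0, 1))
  rownames(scores) <- paste0("s", 1:40)
  pca <- structure(list(scores = scores, n_pcs = 2L,
                        loadings = diag(2), rank = 2L),
                   class = "pca_reduction")
  labs <- rep(c("conferta", "armigera"), each = 20)
  fit <- dapc_fit(pca, labs)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  # sample at a group centroid with >= 10 sd separation: p > 0.99
  near_c1 <- which.min(abs(z - mean(z[1:20])))
  expect_gt(fit$membership[near_c1, "conferta"], 0.99)
  # sample projected midway between centroids gets (0.5, 0.5): symmetry
  mid <- (mean(fit$projection[1:20]) + mean(fit$projection[21:40])) / 2
  s2 <- (sum((fit$projection[1:20] - mean(fit$projection[1:20]))^2) +
         sum((fit$projection[21:40] - mean(fit$projection[21:40]))^2)) / 38
  p_mid <- 1 / (1 + exp((-(mid - mean(fit$projection[1:20]))^2 +
                           (mid - mean(fit$projection[21:40]))^2) / (2 * s2)))
  expect_equal(p_mid, 0.5, tolerance = 1e-12)
})

test_that("the discriminant axis matches a generalized-eigenproblem oracle", {
  d <- make_two_deme_data(15, L = 3000, seed = 32)
  enc <- encode_alignment(d$aln)
  pca <- pca_reduce(enc, 0.30)
  fit <- dapc_fit(pca, d$labs, enc)
  ax <- oracle_discriminant_axis(pca$scores, d$labs)
  expect_gt(abs(stats::cor(fit$discriminant_axis, ax)), 0.999)
  # site loadings: non-negative, one row per contributing site
  expect_true(all(fit$site_loadings$loading >= 0))
})

test_that("admixture classification uses the closed interval", {
  mb <- rbind(c(0.995, 0.005), c(0.5, 0.5), c(0.99, 0.01), c(0.009, 0.991))
  fl <- classify_admixed(mb)
  expect_equal(fl, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(classify_admixed(mb, low = 0.99, high = 0.01),
               class = "bycatchsim_input_error")
})

test_that("admixture-vs-composition regression matches the OLS oracle", {
  mk <- function(n_min, n_maj, n_adm) {
    labs <- c(rep("armigera", n_min), rep("conferta", n_maj))
    adm <- rep(FALSE, n_min + n_maj)
    adm[seq_len(n_adm)] <- TRUE
    list(admixed = adm, labels = labs)
  }
  # exactly linear y in x -> R^2 = 1
  ds <- list(mk(1, 9, 1), mk(2, 8, 2), mk(3, 7, 3))
  expect_equal(admixture_vs_composition(ds)$r_squared, 1, tolerance = 1e-9)
  # generic points against the closed-form oracle
  ds2 <- list(mk(1, 9, 1), mk(2, 8, 2), mk(3, 7, 4), mk(4, 6, 4))
  fit <- admixture_vs_composition(ds2)
  pts <- attr(fit, "points")
  o <- oracle_ols(pts$x, pts$y)
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
  expect_error(admixture_vs_composition(ds[1]),
               class = "bycatchsim_input_error")
})

test_that("sample order does not affect DAPC outputs", {
  d <- make_two_deme_data(10, L = 2000, seed = 33)
  enc <- encode_alignment(d$aln)
  fit <- dapc_fit(pca_reduce(enc, 0.3), d$labs, enc)
  perm <- sample(seq_len(nrow(d$aln)))
  aln_p <- haplo_alignment(unclass(d$aln)[perm, , drop = FALSE])
  enc_p <- encode_alignment(aln_p)
  fit_p <- dapc_fit(pca_reduce(enc_p, 0.3), d$labs[perm], enc_p)
  expect_equal(fit_p$membership[rownames(d$aln), ],
               fit$membership[rownames(d$aln), ], tolerance = 1e-6)
  expect_equal(fit_p$admixed[match(rownames(d$aln), rownames(aln_p))],
               fit$admixed)
})
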
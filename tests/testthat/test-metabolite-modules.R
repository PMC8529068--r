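test_that("bicor matches its defining cases and tracks Pearson on clean data", {
  set.seed(10)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1.0)
  expect_equal(bicor(x, -x), -1.0)
  # large bivariate Gaussian: robust and plain correlation nearly agree
  n <- 1000
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  expect_lt(abs(bicor(x, y) - cor(x, y)), 0.05)
})

test_that("bicor is symmetric and invariant to affine rescaling", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    b <- bicor(x, y)
    expect_equal(bicor(y, x), b)
    expect_equal(bicor(2.5 * x + 7, y), b, tolerance = 1e-12)
    expect_equal(bicor(x, 0.1 * y - 3), b, tolerance = 1e-12)
    expect_gte(b, -1); expect_lte(b, 1)
  }
})

test_that("zero MAD falls back to Pearson deviations with a message", {
  x <- c(rep(1, 28), 5, 9)  # long median run makes the MAD zero
  expect_message(b <- bicor(x, x), "zero MAD")
  expect_equal(b, 1.0)
  y <- c(rep(2, 28), -1, -7)
  suppressMessages(expect_equal(bicor(x, y), cor(x, y), tolerance = 1e-12))
})

test_that("bicor_matrix agrees with the vector form pairwise", {
  set.seed(12)
  d <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
  bm <- bicor_matrix(d)
  expect_true(isSymmetric(bm))
  expect_equal(diag(bm), setNames(rep(1, 6), colnames(d)))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(bm[i, j], bicor(d[, i], d[, j]), tolerance = 1e-12)
})

test_that("signed adjacency maps correlations into [0,1] with closed forms", {
  c_ <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(signed_adjacency(c_, 13), matrix(1, 2, 2))
  c2 <- matrix(c(1, -1, -1, 1), 2)
  a2 <- signed_adjacency(c2, 13)
  expect_equal(a2[1, 2], 0)
  c3 <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(signed_adjacency(c3, 13)[1, 2], 2^-13)
  expect_error(signed_adjacency(c3, 0), "positive")
  expect_error(signed_adjacency(c3 * 2, 2), "\\[-1, 1\\]")
})

test_that("scale-free fit recognizes a power-law degree sequence", {
  # degree sequence with freq(k) ~ k^-2, checked against an independent
  # least-squares fit on the binned log-log data
  ks <- 1:50
  k <- rep(ks, times = round(5000 * ks^-2))
  fit <- scale_free_fit(k, n_bins = 10)
  expect_gte(fit$r_squared, 0.95)
  expect_lt(fit$slope, 0)
  bins <- cut(k, 10)
  ref <- summary(stats::lm(log10(tapply(k, bins, length)) ~
                             log10(tapply(k, bins, mean))))$r.squared
  expect_equal(fit$r_squared, ref, tolerance = 1e-12)
})

test_that("soft threshold selection follows the criterion and its degenerate rules", {
  # block-structured correlations give heterogeneous connectivity
  set.seed(13)
  co <- generate_cohort(cohort_config(seed = 13, n_samples = 100))
  cm <- bicor_matrix(unclass(log2_transform(co$metabolites)))
  ps <- pick_soft_threshold(cm, beta_grid = c(2, 6, 13), r2_target = 0)
  expect_equal(ps$beta, 2)  # target 0: smallest grid power wins
  expect_true(all(diff(ps$scan$mean_connectivity) < 0))
  expect_true(all(ps$scan$r_squared >= 0 & ps$scan$r_squared <= 1, na.rm = TRUE))

  # all-zero correlations: constant connectivity, fall back to grid max
  flat <- diag(10)
  expect_warning(ps0 <- pick_soft_threshold(flat, beta_grid = c(1, 5, 9)),
                 "degenerate")
  expect_equal(ps0$beta, 9)
})

test_that("topological overlap dissimilarity matches the formula on a toy", {
  set.seed(14)
  a <- matrix(runif(16, 0.1, 0.9), 4)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  d <- tom_dissimilarity(a)
  # independent elementwise evaluation
  a0 <- a; diag(a0) <- 0
  k <- colSums(a0)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) { expect_equal(d[i, j], 0); next }
    shared <- sum(a0[i, -c(i, j)] * a0[-c(i, j), j])
    expect_equal(d[i, j],
                 1 - (shared + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("topological overlap hits its boundary cases", {
  # two features adjacent to everything identically: full overlap, d ~ 0
  a <- matrix(1, 5, 5)
  expect_equal(max(tom_dissimilarity(a)), 0, tolerance = 1e-12)
  # isolated non-adjacent pair: d = 1
  a2 <- diag(2)
  expect_equal(tom_dissimilarity(a2)[1, 2], 1)
})

test_that("tree cut recovers planted blocks and obeys min_size", {
  ids <- sprintf("f%02d", 1:20)
  d <- matrix(0.9, 20, 20, dimnames = list(ids, ids))
  d[1:10, 1:10] <- 0.1; d[11:20, 11:20] <- 0.1
  diag(d) <- 0
  part <- cluster_modules(d, deep_split = 4, min_size = 3)
  expect_equal(length(unique(part)), 2L)
  expect_equal(length(unique(part[1:10])), 1L)
  expect_equal(length(unique(part[11:20])), 1L)
  expect_false("unassigned" %in% part)

  # blocks of size 2 below min_size stay unassigned
  ids4 <- sprintf("g%d", 1:4)
  d4 <- matrix(0.9, 4, 4, dimnames = list(ids4, ids4))
  d4[1:2, 1:2] <- 0.1; d4[3:4, 3:4] <- 0.1; diag(d4) <- 0
  expect_true(all(cluster_modules(d4, min_size = 3) == "unassigned"))

  # all pairwise dissimilarities identical: no branch below the cut
  dI <- matrix(0.5, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(dI) <- 0
  expect_true(all(cluster_modules(dI) == "unassigned"))

  # fewer features than min_size
  expect_true(all(cluster_modules(d4[1:2, 1:2], min_size = 3) == "unassigned"))
})

test_that("raising min_size never increases the module count", {
  set.seed(15)
  co <- generate_cohort(cohort_config(seed = 15, n_samples = 80))
  dis <- tom_dissimilarity(signed_adjacency(
    bicor_matrix(unclass(log2_transform(co$metabolites))), 13))
  counts <- vapply(c(3, 5, 8, 12), function(ms) {
    p <- cluster_modules(dis, min_size = ms)
    length(setdiff(unique(p), "unassigned"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("eigenprofiles match the SVD and the degenerate constructions", {
  set.seed(16)
  # k identical profiles: eigenprofile is the standardized common profile
  base <- rnorm(20)
  d <- matrix(rep(base, 4), 20, 4, dimnames = list(NULL, paste0("m", 1:4)))
  part <- setNames(rep("ME1", 4), colnames(d))
  e <- eigenprofiles(d, part)
  expect_equal(e$var_explained[["ME1"]], 1.0, tolerance = 1e-12)
  expect_equal(unname(e$scores[, 1]), as.numeric(scale(base)), tolerance = 1e-8)
  expect_equal(sd(e$scores[, 1]), 1, tolerance = 1e-12)

  # two perfectly anti-correlated members: variance explained 1, orientation
  # by the documented first-member rule
  d2 <- cbind(m1 = base, m2 = -base)
  e2 <- eigenprofiles(d2, setNames(rep("ME1", 2), colnames(d2)))
  expect_equal(e2$var_explained[["ME1"]], 1.0, tolerance = 1e-12)
  expect_gt(cor(e2$scores[, 1], d2[, "m1"]), 0)

  # 5 modules x 20 samples toy against a direct SVD oracle
  d3 <- matrix(rnorm(20 * 15), 20, 15, dimnames = list(NULL, sprintf("x%02d", 1:15)))
  part3 <- setNames(rep(sprintf("ME%d", 1:5), each = 3), colnames(d3))
  e3 <- eigenprofiles(d3, part3)
  for (m in sprintf("ME%d", 1:5)) {
    xm <- scale(d3[, names(part3)[part3 == m]])
    sv <- svd(xm)
    ref <- sv$u[, 1] * sv$d[1]
    ref <- ref / sd(ref)
    agree <- min(sum(abs(e3$scores[, m] - ref)), sum(abs(e3$scores[, m] + ref)))
    expect_lt(agree, 1e-8)
    expect_equal(e3$var_explained[[m]], sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-12)
  }
  expect_error(eigenprofiles(d3, setNames("ME9", colnames(d3)[1])), "fewer than 2")
})

test_that("unassigned features are rescued by eigenprofile correlation when data given", {
  set.seed(17)
  f <- rnorm(60)
  block <- sapply(1:6, function(i) f + 0.3 * rnorm(60))
  lone <- f + 0.4 * rnorm(60)          # correlated straggler
  noise <- matrix(rnorm(60 * 2), 60, 2) # uncorrelated stragglers
  d <- cbind(block, lone, noise)
  colnames(d) <- sprintf("f%d", 1:9)
  cm <- bicor_matrix(d)
  dis <- tom_dissimilarity(signed_adjacency(cm, 6))
  part <- cluster_modules(dis, min_size = 5, data = d)
  expect_equal(unname(part["f7"]), unname(part["f1"]))
  expect_true(all(part[c("f8", "f9")] == "unassigned"))
})
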
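#' Bray-Curtis distance matrix
#'
#' `d_ij = sum|x - y| / sum(x + y)` over features, via
#' [vegan::vegdist()]; identical samples have distance 0, samples with
#' disjoint support distance 1.
#'
#' @param matrix nonnegative [omics_matrix()] or plain matrix
#'   (samples x features).
#' @return symmetric distance matrix (base `matrix`).
#' @export
bray_curtis <- function(matrix) {
  v <- if (inherits(matrix, "omics_matrix")) .values(matrix) else as.matrix(matrix)
  if (any(v < 0, na.rm = TRUE)) stop("bray_curtis needs nonnegative values")
  if (sum(rowSums(v) == 0) >= 2L)
    stop("two or more all-zero samples: Bray-Curtis undefined for their pair")
  as.matrix(vegan::vegdist(v, method = "bray"))
}

#' Single-variable PERMANOVA
#'
#' Permutational multivariate analysis of variance of a distance matrix
#' against one numeric covariate (binary or continuous). The squared
#' distance matrix is Gower-centered, `G = -1/2 J D^2 J`; the model sum of
#' squares is the quadratic form of G on the standardized centered
#' covariate, `r^2 = SS_model / SS_total`, and the pseudo-F statistic is
#' referenced to its permutation distribution under random relabeling of the
#' covariate, with the add-one rule
#' `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)` (p is never reported as 0).
#' `r^2` is invariant to affine rescaling of the covariate.
#'
#' @param d distance matrix (square symmetric) or `dist`.
#' @param v numeric covariate aligned to the rows of `d`; must not be
#'   constant.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `r_squared`, `f`, `p`, `n_perm`.
#' @export
permanova <- function(d, v, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(v) != n) stop("covariate length must match the distance matrix")
  if (anyNA(v)) {
    keep <- !is.na(v)
    d <- d[keep, keep, drop = FALSE]; v <- v[keep]; n <- length(v)
  }
  if (n < 4L) stop("permanova needs >= 4 non-missing samples")
  if (length(unique(v)) < 2L) stop("constant covariate")
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (d^2) %*% J
  ss_tot <- sum(diag(G))
  vc <- v - mean(v)
  u <- vc / sqrt(sum(vc^2))
  ss_m <- drop(crossprod(u, G %*% u))
  r2 <- ss_m / ss_tot
  f_obs <- (ss_m / 1) / ((ss_tot - ss_m) / (n - 2))
  set.seed(seed)
  U <- vapply(seq_len(n_perm), function(i) u[sample.int(n)], numeric(n))
  ss_perm <- colSums((G %*% U) * U)
  f_perm <- ss_perm / ((ss_tot - ss_perm) / (n - 2))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  list(r_squared = r2, f = f_obs, p = p, n_perm = n_perm)
}

#' PERMANOVA screen over the columns of a phenotype table
#'
#' Runs [permanova()] of every phenotype variable against one distance
#' matrix and ranks the results by effect size.
#'
#' @param d distance matrix over samples.
#' @param phenotypes [omics_matrix()] (samples x variables), missing values
#'   handled by per-variable case deletion.
#' @param n_perm,seed passed to [permanova()].
#' @return data.frame (`variable`, `r_squared`, `f`, `p`, `q`) sorted by
#'   decreasing `r_squared`, with BH q across the screen.
#' @export
permanova_screen <- function(d, phenotypes, n_perm = 999, seed = 1) {
  vars <- colnames(phenotypes)
  res <- lapply(seq_along(vars), function(j) {
    v <- .values(phenotypes)[, j]
    if (length(unique(v[!is.na(v)])) < 2L) return(NULL)
    r <- permanova(d, v, n_perm = n_perm, seed = .stage_seed(seed, vars[j]))
    data.frame(variable = vars[j], r_squared = r$r_squared, f = r$f, p = r$p)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[order(-out$r_squared), ]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` counts pairs where a value from `a` exceeds
#' one from `b` (ties count 1/2), so `U = 0` means every `a` is below every
#' `b`. For `n_a + n_b <= 12` the exact permutation distribution of U is
#' enumerated (ties handled through mid-ranks); otherwise the normal
#' approximation with tie correction (no continuity correction) is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `u`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (n <= 12L) {
    combos <- combn(n, na)
    us <- colSums(array(r[combos], dim(combos))) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    list(u = u, p = p, method = "exact")
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
    z <- (u - na * nb / 2) / sqrt(sigma2)
    list(u = u, p = 2 * pnorm(-abs(z)), method = "normal")
  }
}

#' Per-feature differential abundance between two groups
#'
#' [mann_whitney()] on every feature of a matrix against a binary grouping,
#' with the direction sign taken from the group-median difference
#' (group 1 minus group 0) and a BH q-value across features.
#'
#' @param matrix [omics_matrix()] (samples x features).
#' @param labels binary vector (0/1, logical, or 2-level factor) aligned to
#'   samples; group "1" is the case group.
#' @return data.frame (`feature`, `u`, `p`, `q`, `direction`) sorted by `p`.
#' @export
differential_abundance <- function(matrix, labels) {
  g <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(g[!is.na(g)])) != 2L) stop("labels must have exactly two levels")
  v <- .values(matrix)
  res <- lapply(colnames(v), function(f) {
    x1 <- v[g == 1L, f]; x0 <- v[g == 0L, f]
    mw <- mann_whitney(x1, x0)
    data.frame(feature = f, u = mw$u, p = mw$p,
               direction = sign(median(x1, na.rm = TRUE) - median(x0, na.rm = TRUE)))
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), c("feature", "u", "p", "q", "direction")]
  rownames(out) <- NULL
  out
}

#' Reporter scores for functional modules
#'
#' Aggregates per-feature significance into module-level Z-scores:
#' `z_i = qnorm(1 - p_i)` signed by the feature's direction,
#' `Z_module = sum(z_i) / sqrt(k)` over the `k` members, background-corrected
#' as `(Z_module - mu_k) / sigma_k` where `mu_k` and `sigma_k` are the mean
#' and standard deviation of the same aggregate over `n_draws` random size-k
#' feature sets drawn from the full background. Modules with
#' `|corrected Z| >= z_threshold` are flagged significant.
#'
#' @param module_map data.frame with columns `feature`, `module`
#'   (many-to-many allowed); every member must have a p-value.
#' @param feature_p named vector of per-feature p-values.
#' @param feature_dir named vector of direction signs (+1/-1; 0 allowed).
#' @param n_draws background draws per module size.
#' @param z_threshold significance cutoff on the corrected score.
#' @param seed RNG seed for the background draws.
#' @return data.frame (`module`, `k`, `z_raw`, `z_corrected`,
#'   `significant`).
#' @export
reporter_score <- function(module_map, feature_p, feature_dir,
                           n_draws = 1000, z_threshold = 1.96, seed = 1) {
  stopifnot(all(c("feature", "module") %in% names(module_map)))
  missing <- setdiff(module_map$feature, names(feature_p))
  if (length(missing) > 0L)
    stop("module member(s) without a p-value: ", paste(head(missing, 5), collapse = ", "))
  p <- pmin(pmax(feature_p, 1e-15), 1 - 1e-15)
  z <- qnorm(1 - p)
  dirs <- feature_dir[names(p)]
  dirs[is.na(dirs)] <- 0
  z <- z * sign(dirs)
  modules <- unique(module_map$module)
  set.seed(seed)
  bg <- z
  ks <- vapply(modules, function(m) sum(module_map$module == m), integer(1))
  mu_sd <- lapply(sort(unique(ks)), function(k) {
    draws <- vapply(seq_len(n_draws),
                    function(i) sum(bg[sample.int(length(bg), k)]) / sqrt(k),
                    numeric(1))
    s <- sd(draws)
    if (is.na(s) || s == 0) stop("degenerate background for module size ", k)
    c(mu = mean(draws), sigma = s)
  })
  names(mu_sd) <- as.character(sort(unique(ks)))
  out <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[i]; k <- ks[i]
    zr <- sum(z[module_map$feature[module_map$module == m]]) / sqrt(k)
    ms <- mu_sd[[as.character(k)]]
    zc <- (zr - ms["mu"]) / ms["sigma"]
    data.frame(module = m, k = k, z_raw = zr, z_corrected = unname(zc),
               significant = abs(zc) >= z_threshold)
  }))
  rownames(out) <- NULL
  out
}
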
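#' Biweight midcorrelation
#'
#' Robust correlation built on Tukey biweights around the median:
#' `u_i = (x_i - med(x)) / (9 * mad(x))`, weights
#' `w_i = (1 - u_i^2)^2 * 1(|u_i| < 1)`, and the correlation of the
#' weighted deviations. When a vector's MAD is zero the weights are
#' undefined; that side falls back to ordinary centered (Pearson) deviations
#' and a message is emitted.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("bicor needs two vectors of equal length >= 3")
  xt <- .bicor_deviations(x)
  yt <- .bicor_deviations(y)
  den <- sqrt(sum(xt^2)) * sqrt(sum(yt^2))
  if (den == 0) return(NA_real_)
  max(-1, min(1, sum(xt * yt) / den))
}

.bicor_deviations <- function(x, label = NULL) {
  med <- median(x)
  m <- mad(x, constant = 1)
  if (m == 0) {
    message("bicor: zero MAD", if (!is.null(label)) paste0(" for ", label),
            "; falling back to Pearson deviations")
    return(x - mean(x))
  }
  u <- (x - med) / (9 * m)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' All-pairs biweight midcorrelation matrix
#'
#' Column-pairwise [bicor()] of a samples x features matrix. Because the
#' biweights of a column do not depend on the pairing, the matrix form is a
#' normalized cross-product of per-column weighted deviations and agrees
#' exactly with the vector form.
#'
#' @param data numeric matrix, samples in rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop("bicor_matrix needs >= 3 samples")
  dev <- data
  for (j in seq_len(ncol(data)))
    dev[, j] <- .bicor_deviations(data[, j], label = colnames(data)[j])
  nrm <- sqrt(colSums(dev^2))
  nrm[nrm == 0] <- NA_real_
  dev <- sweep(dev, 2, nrm, "/")
  c_ <- crossprod(dev)
  c_[c_ > 1] <- 1; c_[c_ < -1] <- -1
  diag(c_) <- 1
  c_
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + c_ij) / 2)^beta` with unit diagonal: a signed network in
#' which strong negative correlations map near 0 and strong positive ones
#' near 1.
#'
#' @param cor_mat symmetric correlation matrix with entries in `[-1, 1]`.
#' @param beta soft-threshold power, > 0.
#' @return symmetric adjacency in `[0, 1]`.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a positive scalar")
  if (any(abs(cor_mat) > 1 + 1e-8, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into equal-width bins and regresses
#' `log10(frequency)` on `log10(mean binned connectivity)`; returns the
#' coefficient of determination and the slope. `NA` when fewer than three
#' populated bins exist (degenerate, e.g. near-constant connectivity).
#'
#' @param k nonnegative connectivity vector.
#' @param n_bins number of bins.
#' @return list with `r_squared` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 3L || diff(range(k)) < .Machine$double.eps^0.5 * max(k))
    return(list(r_squared = NA_real_, slope = NA_real_))
  bins <- cut(k, n_bins)
  kmean <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length)
  ok <- !is.na(kmean) & freq > 0
  if (sum(ok) < 3L) return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  list(r_squared = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' Scans a grid of powers; for each, forms the signed adjacency, computes the
#' whole-network connectivity `k_i = sum_j a_ij - 1`, and evaluates
#' [scale_free_fit()]. The chosen power is the smallest grid value whose fit
#' R-squared reaches `r2_target`; if none does, the argmax of R-squared. If
#' every fit is degenerate (constant connectivity) the largest grid power is
#' returned with a warning.
#'
#' @param cor_mat symmetric correlation matrix.
#' @param beta_grid candidate powers.
#' @param r2_target R-squared target.
#' @return list with `beta` and `scan`, a data.frame with one row per power
#'   (`beta`, `r_squared`, `slope`, `mean_connectivity`).
#' @export
pick_soft_threshold <- function(cor_mat, beta_grid = 1:20, r2_target = 0.85) {
  if (length(beta_grid) < 1L) stop("beta_grid must be non-empty")
  beta_grid <- sort(unique(beta_grid))
  scan <- do.call(rbind, lapply(beta_grid, function(b) {
    a <- signed_adjacency(cor_mat, b)
    k <- colSums(a) - 1
    fit <- scale_free_fit(k)
    data.frame(beta = b, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = mean(k))
  }))
  if (all(is.na(scan$r_squared))) {
    warning("degenerate connectivity at every power; returning the largest grid value")
    return(list(beta = max(beta_grid), scan = scan))
  }
  hit <- which(!is.na(scan$r_squared) & scan$r_squared >= r2_target)
  beta <- if (length(hit) > 0L) scan$beta[hit[1L]] else scan$beta[which.max(scan$r_squared)]
  list(beta = beta, scan = scan)
}

#' Topological overlap dissimilarity
#'
#' `d_ij = 1 - (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' zero diagonal, where `k` is the connectivity excluding the self-edge. Two
#' features that share all their neighborhood have dissimilarity near 0; an
#' isolated non-adjacent pair has dissimilarity 1.
#'
#' @param adjacency symmetric matrix in `[0, 1]`.
#' @return symmetric dissimilarity matrix in `[0, 1]`.
#' @export
tom_dissimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < -1e-12 | a > 1 + 1e-12, na.rm = TRUE))
    stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- colSums(a)
  shared <- a %*% a
  den <- outer(k, k, pmin) + 1 - a
  d <- 1 - (shared + a) / den
  d[d < 0] <- 0; d[d > 1] <- 1
  diag(d) <- 0
  dimnames(d) <- dimnames(adjacency)
  d
}

#' Cluster features into co-abundance modules
#'
#' Average-linkage hierarchical clustering of a dissimilarity matrix followed
#' by an adaptive static cut: the tree is cut at
#' `(1 - 0.01 * (deep_split + 1)) * h_max`, a fixed fraction of the maximal
#' merge height, so a higher `deep_split` cuts lower and yields finer
#' branches (deep split 4 cuts at 95% of the tree height, deep split 0 at
#' 99%). Cutting relative to the top of the tree is what separates planted
#' co-abundance blocks from the unrelated-feature plateau, where merges
#' concentrate just below the maximal height. Branches smaller than
#' `min_size` are labeled `"unassigned"`. When `data` is supplied, each
#' unassigned feature is rescued into the module whose eigenprofile it
#' correlates with best, provided that correlation is at least
#' `reassign_cor`. If all pairwise dissimilarities are identical every merge
#' sits at the (single) maximal height, nothing falls below the cut, and all
#' features are unassigned.
#'
#' @param dissimilarity square symmetric dissimilarity matrix with feature
#'   dimnames (e.g. from [tom_dissimilarity()]).
#' @param deep_split integer 0..4, branch-splitting sensitivity.
#' @param min_size minimum module size (default 3).
#' @param data optional samples x features matrix (same features) used for
#'   the eigenprofile rescue step; `NULL` disables it.
#' @param reassign_cor minimum signed correlation for rescue.
#' @return named character vector feature -> module id (`"ME1"`, `"ME2"`,
#'   ... in decreasing size order) or `"unassigned"`.
#' @export
cluster_modules <- function(dissimilarity, deep_split = 4, min_size = 3,
                            data = NULL, reassign_cor = 0.3) {
  d <- as.matrix(dissimilarity)
  feats <- colnames(d)
  if (is.null(feats)) feats <- paste0("F", seq_len(ncol(d)))
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  n <- ncol(d)
  if (n < min_size)
    return(setNames(rep("unassigned", n), feats))
  hc <- hclust(as.dist(d), method = "average")
  cut_h <- (1 - 0.01 * (deep_split + 1)) * max(hc$height)
  labels <- if (max(hc$height) <= 0) setNames(rep(1L, n), feats) else
    cutree(hc, h = cut_h)
  tab <- table(labels)
  keep <- names(tab)[tab >= min_size]
  out <- rep("unassigned", n)
  names(out) <- feats
  if (length(keep) > 0L) {
    keep <- keep[order(-tab[keep], as.integer(keep))]
    for (i in seq_along(keep))
      out[labels == as.integer(keep[i])] <- sprintf("ME%d", i)
  }
  if (!is.null(data) && any(out == "unassigned") && any(out != "unassigned")) {
    eig <- eigenprofiles(data, out)
    for (f in names(out)[out == "unassigned"]) {
      r <- suppressWarnings(cor(data[, f], eig$scores))
      r[is.na(r)] <- -Inf
      best <- which.max(r)
      if (r[best] >= reassign_cor) out[f] <- colnames(eig$scores)[best]
    }
  }
  out
}

#' Module eigenprofiles
#'
#' Summarizes each module by the first principal component of its
#' standardized member submatrix: per-sample scores scaled to unit variance,
#' sign-oriented so the correlation with the member-mean profile is
#' nonnegative (when the member mean is constant, orientation falls back to
#' nonnegative correlation with the first member). The fraction of member
#' variance explained by the component is reported.
#'
#' @param data samples x features numeric matrix.
#' @param partition named vector feature -> module label; `"unassigned"` is
#'   skipped. Every module needs >= 2 members present in `data`.
#' @return list with `scores` (samples x modules matrix, unit variance
#'   columns) and `var_explained` (named vector).
#' @export
eigenprofiles <- function(data, partition) {
  data <- as.matrix(data)
  modules <- setdiff(unique(partition), "unassigned")
  modules <- modules[order(as.integer(sub("^ME", "", modules)))]
  if (length(modules) == 0L) stop("no assigned modules in partition")
  scores <- matrix(NA_real_, nrow(data), length(modules),
                   dimnames = list(rownames(data), modules))
  ve <- setNames(numeric(length(modules)), modules)
  for (m in modules) {
    members <- names(partition)[partition == m]
    missing <- setdiff(members, colnames(data))
    if (length(missing) > 0L)
      stop("module ", m, " member(s) absent from data: ",
           paste(head(missing, 5), collapse = ", "))
    if (length(members) < 2L) stop("module ", m, " has fewer than 2 members")
    x <- scale(data[, members, drop = FALSE])
    x[, !is.finite(colSums(x))] <- 0 # constant members carry no signal
    sv <- svd(x)
    sc <- sv$u[, 1L] * sv$d[1L]
    if (sd(sc) == 0) stop("degenerate eigenprofile for module ", m)
    sc <- sc / sd(sc)
    ref <- rowMeans(x)
    orient <- if (sd(ref) > 0) cor(sc, ref) else cor(sc, x[, 1L])
    if (!is.na(orient) && orient < 0) sc <- -sc
    scores[, m] <- sc
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(scores = scores, var_explained = ve)
}
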
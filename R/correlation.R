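#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties receive average ranks) with a
#' two-sided p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; `|rho| = 1` gives `p = 0`. Incomplete pairs are
#' dropped (pairwise deletion).
#'
#' @param x,y numeric vectors; at least 4 complete pairs required.
#' @return list with `rho`, `p`, `n` (complete pairs used) and `ok`
#'   (`FALSE` with `rho = NA` when either vector is constant on the
#'   complete pairs).
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("spearman_cor needs >= 4 complete pairs (got ", n, ")")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE))
  rho <- cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, ok = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted q-values,
#' `q_(i) = min_(j >= i) m p_(j) / j`, via [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return q-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' All-pairs Spearman screen between (or within) domains
#'
#' One correlation edge per feature pair: every column of `a` against every
#' column of `b`, or all unordered distinct pairs within `a` when `b` is
#' omitted. Complete columns are ranked once and correlated by matrix
#' product; columns with missing values (phenotype tables) use per-pair
#' pairwise deletion with re-ranking. Pairs with fewer than 4 complete
#' observations, or with a constant vector, get `NA` statistics and are
#' counted in a message.
#'
#' @param a,b aligned [omics_matrix()] objects (same samples, same order).
#' @param add_q add a BH q-value column computed over this screen (one
#'   domain-pair family per call).
#' @return data.frame with columns `feature_a`, `domain_a`, `feature_b`,
#'   `domain_b`, `rho`, `p`, `q` (if requested), `n_used`.
#' @export
correlate_pairs <- function(a, b = NULL, add_q = TRUE) {
  within <- is.null(b)
  if (within) b <- a
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b)))
    stop("matrices must be sample-aligned; see align_samples()")
  da <- omics_domain(a) %||% "unknown"
  db <- omics_domain(b) %||% "unknown"
  va <- .values(a); vb <- .values(b)
  n <- nrow(va)

  pairs <- if (within) {
    idx <- combn(ncol(va), 2L)
    data.frame(i = idx[1L, ], j = idx[2L, ])
  } else {
    expand.grid(i = seq_len(ncol(va)), j = seq_len(ncol(vb)))
  }
  edges <- data.frame(
    feature_a = colnames(va)[pairs$i], domain_a = da,
    feature_b = colnames(vb)[pairs$j], domain_b = db,
    rho = NA_real_, p = NA_real_, n_used = NA_integer_,
    stringsAsFactors = FALSE)

  ca <- colSums(is.na(va)) == 0L
  cb <- colSums(is.na(vb)) == 0L
  fast <- ca[pairs$i] & cb[pairs$j]

  if (any(fast)) {
    ra <- apply(va[, unique(pairs$i[fast]), drop = FALSE], 2L, rank)
    rb <- apply(vb[, unique(pairs$j[fast]), drop = FALSE], 2L, rank)
    sda <- apply(ra, 2L, sd); sdb <- apply(rb, 2L, sd)
    rmat <- suppressWarnings(cor(ra, rb))
    ii <- match(pairs$i[fast], unique(pairs$i[fast]))
    jj <- match(pairs$j[fast], unique(pairs$j[fast]))
    rho <- rmat[cbind(ii, jj)]
    rho[sda[ii] == 0 | sdb[jj] == 0] <- NA_real_
    rho <- pmax(-1, pmin(1, rho))
    p <- ifelse(abs(rho) >= 1, 0,
                2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2))
    edges$rho[fast] <- rho
    edges$p[fast] <- p
    edges$n_used[fast] <- n
  }
  slow <- which(!fast)
  for (k in slow) {
    x <- va[, pairs$i[k]]; y <- vb[, pairs$j[k]]
    nc <- sum(complete.cases(x, y))
    edges$n_used[k] <- nc
    if (nc < 4L) next
    s <- spearman_cor(x, y)
    if (s$ok) { edges$rho[k] <- s$rho; edges$p[k] <- s$p }
  }
  n_bad <- sum(is.na(edges$rho))
  if (n_bad > 0L)
    message("correlate_pairs: ", n_bad, " pair(s) skipped (constant vector or < 4 complete pairs)")
  if (add_q) edges$q <- bh_adjust(edges$p)
  edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Triangular retention of cross-domain feature triples
#'
#' A (microbiome feature, metabolite group, phenotype) triple is retained iff
#' all three of its pairwise correlation legs are significant at
#' `p < p_threshold`. Retained features are those appearing in at least one
#' retained triple.
#'
#' @param e_mgs_phe,e_met_phe,e_mgs_met edge data.frames from
#'   [correlate_pairs()] for the three screens (microbiome x phenotype,
#'   metabolite x phenotype, microbiome x metabolite); `feature_a` must be
#'   the microbiome / metabolite / microbiome side respectively.
#' @param p_threshold retention threshold on each leg.
#' @return list with `triangles` (data.frame `mgs`, `metabolite`,
#'   `phenotype` plus the three rho/p pairs) and `retained`, a list of
#'   per-domain retained feature id vectors.
#' @export
triangular_retention <- function(e_mgs_phe, e_met_phe, e_mgs_met,
                                 p_threshold = 0.05) {
  keep <- function(e) e[!is.na(e$p) & e$p < p_threshold, , drop = FALSE]
  a <- keep(e_mgs_phe); b <- keep(e_met_phe); c_ <- keep(e_mgs_met)
  ab <- merge(
    data.frame(mgs = a$feature_a, phenotype = a$feature_b,
               rho_mgs_phe = a$rho, p_mgs_phe = a$p),
    data.frame(metabolite = b$feature_a, phenotype = b$feature_b,
               rho_met_phe = b$rho, p_met_phe = b$p),
    by = "phenotype")
  tri <- merge(
    ab,
    data.frame(mgs = c_$feature_a, metabolite = c_$feature_b,
               rho_mgs_met = c_$rho, p_mgs_met = c_$p),
    by = c("mgs", "metabolite"))
  tri <- tri[order(tri$mgs, tri$metabolite, tri$phenotype),
             c("mgs", "metabolite", "phenotype",
               "rho_mgs_phe", "p_mgs_phe", "rho_met_phe", "p_met_phe",
               "rho_mgs_met", "p_mgs_met")]
  rownames(tri) <- NULL
  list(triangles = tri,
       retained = list(mgs = unique(tri$mgs),
                       metabolite = unique(tri$metabolite),
                       phenotype = unique(tri$phenotype)))
}

#' Filter correlation edges for community analysis
#'
#' Keeps an edge iff its BH q-value is below `q_max`, `|rho| >= rho_min`
#' (the boundary value is kept), and the two features come from different
#' domains (only inter-omic correlations enter the network).
#'
#' @param edges edge data.frame (or an `rbind` of several screens, each with
#'   q computed within its own domain-pair family).
#' @param q_max,rho_min thresholds.
#' @return the filtered edge data.frame.
#' @export
filter_for_network <- function(edges, q_max = 0.1, rho_min = 0.3) {
  stopifnot(all(c("feature_a", "feature_b", "rho", "q") %in% names(edges)))
  keep <- !is.na(edges$q) & !is.na(edges$rho) &
    edges$q < q_max & abs(edges$rho) >= rho_min &
    edges$domain_a != edges$domain_b
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
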
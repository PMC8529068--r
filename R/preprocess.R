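#' MGS abundance from constituent gene abundances
#'
#' The relative abundance of a metagenomic species (MGS) is the arithmetic
#' mean of the relative abundances of its constituent genes, per sample.
#'
#' @param gene_matrix [omics_matrix()] of gene relative abundances
#'   (samples x genes).
#' @param map data.frame with columns `feature` (gene id) and `module`
#'   (MGS id), every MGS mapping to >= 1 gene present in the matrix.
#' @return [omics_matrix()] of MGS abundances, domain `microbiome_mgs`.
#' @export
mgs_abundance <- function(gene_matrix, map) {
  stopifnot(is.data.frame(map), all(c("feature", "module") %in% names(map)))
  missing <- setdiff(map$feature, colnames(gene_matrix))
  if (length(missing) > 0L)
    stop("mapped gene(s) absent from matrix: ", paste(head(missing, 5), collapse = ", "))
  mgs_ids <- unique(map$module)
  out <- vapply(mgs_ids, function(m) {
    genes <- map$feature[map$module == m]
    if (length(genes) == 0L) stop("MGS with zero mapped genes: ", m)
    rowMeans(.values(gene_matrix)[, genes, drop = FALSE])
  }, numeric(nrow(gene_matrix)))
  if (nrow(gene_matrix) == 1L) out <- matrix(out, 1L, dimnames = list(rownames(gene_matrix), mgs_ids))
  omics_matrix(out, "microbiome_mgs")
}

#' Prevalence filter
#'
#' Keeps a feature iff it is non-zero in strictly more than `min_fraction` of
#' samples (the conventional strict ">10% of samples" rule at the default).
#' Idempotent; never increases the feature count.
#'
#' @param matrix an [omics_matrix()].
#' @param min_fraction strict lower bound on the non-zero sample fraction.
#' @return the filtered [omics_matrix()].
#' @export
prevalence_filter <- function(matrix, min_fraction = 0.10) {
  prev <- colMeans(.values(matrix) != 0, na.rm = TRUE)
  keep <- prev > min_fraction
  omics_matrix(.values(matrix)[, keep, drop = FALSE], omics_domain(matrix))
}

#' Per-sample Shannon alpha-diversity (natural log)
#'
#' `H = -sum p_i log p_i` over the renormalized non-zero features of each
#' sample; invariant to rescaling a sample by a common factor. Delegates to
#' [vegan::diversity()].
#'
#' @param matrix nonnegative [omics_matrix()] (samples x features).
#' @return named numeric vector of H per sample.
#' @export
shannon_diversity <- function(matrix) {
  v <- .values(matrix)
  if (any(v < 0, na.rm = TRUE)) stop("shannon_diversity needs nonnegative values")
  zero <- rowSums(v, na.rm = TRUE) == 0
  if (any(zero)) stop("all-zero sample(s): ", paste(rownames(v)[zero], collapse = ", "))
  vegan::diversity(v, index = "shannon")
}

#' Per-sample richness
#'
#' Count of strictly positive features per sample.
#'
#' @param matrix an [omics_matrix()].
#' @return named integer vector.
#' @export
richness <- function(matrix) {
  rowSums(.values(matrix) > 0, na.rm = TRUE)
}

#' Log2 transform with pseudocount
#'
#' `x -> log2(x + pseudocount)`. The default pseudocount is half the smallest
#' non-zero value of the matrix (scale-aware, avoids -Inf on exact zeros).
#'
#' @param matrix nonnegative [omics_matrix()] or plain matrix.
#' @param pseudocount nonnegative scalar added before taking logs.
#' @return matrix of the same shape (and class, for omics matrices).
#' @export
log2_transform <- function(matrix, pseudocount = NULL) {
  v <- if (inherits(matrix, "omics_matrix")) .values(matrix) else as.matrix(matrix)
  if (any(v < 0, na.rm = TRUE)) stop("log2_transform needs nonnegative values")
  if (is.null(pseudocount)) {
    nz <- v[v > 0]
    pseudocount <- if (length(nz) > 0L && any(v == 0, na.rm = TRUE)) min(nz) / 2 else 0
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  out <- log2(v + pseudocount)
  if (inherits(matrix, "omics_matrix")) {
    attr(out, "domain") <- omics_domain(matrix)
    class(out) <- class(matrix)
  }
  out
}
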
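#' @useDynLib trinetomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test median mad prcomp pnorm pt qnorm quantile
#'   rnorm runif rbinom sd setNames var hclust cutree as.dist complete.cases
#'   p.adjust plogis qlogis
#' @importFrom utils read.delim write.table combn head
NULL

.DOMAINS <- c("microbiome_mgs", "microbiome_function", "metabolite", "phenotype")

#' Samples-by-features omics matrix
#'
#' The shared container for all pipeline stages: a numeric matrix with samples
#' in rows and features in columns, tagged with the omics domain it came from.
#' On disk (see [read_omics_matrix()]) the transposed orientation is used
#' (features in rows, samples in columns), the prevailing dialect for
#' abundance tables.
#'
#' @param values numeric matrix, samples x features, with unique non-empty
#'   rownames (sample ids) and colnames (feature ids).
#' @param domain one of `"microbiome_mgs"`, `"microbiome_function"`,
#'   `"metabolite"`, `"phenotype"`.
#' @return An object of class `omics_matrix` (a numeric matrix with a
#'   `domain` attribute).
#' @details Missing values are permitted only in the `phenotype` domain
#'   (clinical tables are sparse); all-`NA` feature columns are rejected in
#'   every domain.
#' @export
omics_matrix <- function(values, domain = .DOMAINS) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("omics_matrix values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics_matrix needs sample rownames and feature colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!nzchar(rownames(values))) || any(!nzchar(colnames(values))))
    stop("empty sample or feature id")
  if (anyNA(values)) {
    if (domain != "phenotype")
      stop("missing values are only allowed in the phenotype domain")
    all_na <- colSums(!is.na(values)) == 0L
    if (any(all_na))
      stop("all-NA feature columns: ", paste(colnames(values)[all_na], collapse = ", "))
  }
  structure(values, domain = domain, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> domain=%s, %d samples x %d features\n",
              attr(x, "domain"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x object to query.
#' @export
omics_domain <- function(x) attr(x, "domain")

# strip class/attr, keep plain matrix
.values <- function(x) {
  y <- unclass(x)
  attr(y, "domain") <- NULL
  y
}

#' Read / write an omics matrix as tab-separated text
#'
#' On-disk layout: features in rows, samples in columns, a header row of
#' sample ids, and feature ids in the first column (header `feature_id`).
#' `read_omics_matrix(write_omics_matrix(m, f), domain)` reproduces `m` to
#' better than 1e-12 relative error.
#'
#' @param path file path.
#' @param domain the domain tag to attach (see [omics_matrix()]).
#' @return `read_omics_matrix`: an [omics_matrix()]. `write_omics_matrix`:
#'   `path`, invisibly.
#' @export
read_omics_matrix <- function(path, domain = .DOMAINS) {
  domain <- match.arg(domain)
  nfields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nfields)) != 1L)
    stop("ragged TSV '", path, "': rows ", paste(which(nfields != nfields[1]), collapse = ","),
         " have a different number of fields")
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("matrix TSV needs a feature id column plus >=1 sample")
  feat <- raw[[1L]]
  if (anyDuplicated(feat))
    stop("duplicated feature id(s) in '", path, "': ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN", "")) , arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell in '%s' at feature '%s', sample '%s': '%s'",
                 path, feat[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  m <- t(num)
  colnames(m) <- feat
  omics_matrix(m, domain)
}

#' @rdname read_omics_matrix
#' @param matrix an [omics_matrix()] (or any samples x features matrix).
#' @export
write_omics_matrix <- function(matrix, path) {
  m <- t(.values(matrix))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict matrices to their common samples, in a common order
#'
#' @param ... two or more [omics_matrix()] objects (or a single list of them).
#' @return A list of matrices restricted to the shared sample ids, in the
#'   order they appear in the first matrix. Dropped samples are reported via
#'   `message()`.
#' @export
align_samples <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  if (length(mats) < 2L) stop("align_samples needs at least two matrices")
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L) stop("no samples shared across matrices")
  common <- rownames(mats[[1L]])[rownames(mats[[1L]]) %in% common]
  out <- lapply(mats, function(m) {
    dropped <- setdiff(rownames(m), common)
    if (length(dropped) > 0L)
      message("align_samples: dropping ", length(dropped), " sample(s): ",
              paste(head(dropped, 5L), collapse = ", "),
              if (length(dropped) > 5L) ", ..." else "")
    m[common, , drop = FALSE]
  })
  names(out) <- names(mats)
  out
}

#' Read a feature-to-module map
#'
#' Two-column tab-separated file (`feature_id`, `module_id`), many-to-many
#' allowed, used e.g. to map KO gene families to KEGG modules or gut
#' metabolic modules (GMMs) for reporter scoring.
#'
#' @param path file path.
#' @return data.frame with columns `feature` and `module`.
#' @export
read_feature_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("feature map needs two columns: feature_id, module_id")
  out <- data.frame(feature = df[[1L]], module = df[[2L]], stringsAsFactors = FALSE)
  if (any(!nzchar(out$feature)) || any(!nzchar(out$module)))
    stop("feature map contains empty ids")
  out
}

#' @rdname read_feature_map
#' @param map data.frame with columns `feature`, `module`.
#' @export
write_feature_map <- function(map, path) {
  write.table(data.frame(feature_id = map$feature, module_id = map$module),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
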
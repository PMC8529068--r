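#' Synthetic trans-omics cohort configuration
#'
#' Parameters of the latent-factor generator used to validate the pipeline
#' end to end. Defaults emulate the target study design: 138 subjects, three
#' sample-aligned domains (compositional zero-inflated microbiome, log-normal
#' urine metabolome grouped into co-abundant modules, continuous blood
#' biomarkers plus a binary disease label), and a latent-factor covariance
#' structure that plants known cross-domain correlations.
#'
#' @param n_samples number of subjects.
#' @param n_mgs number of metagenomic species (MGS) features; half of them
#'   load on latent factors, the rest are independent noise.
#' @param n_metabolites number of urine metabolite features; each factor owns
#'   one co-abundant module, remaining features are noise.
#' @param n_biomarkers number of continuous blood biomarkers; one per factor
#'   loads on that factor, the rest are independent (disease drivers are
#'   drawn from the independent ones, so the microbiome carries no label
#'   signal by construction).
#' @param n_factors number of latent factors (= number of planted metabolite
#'   modules).
#' @param lambda factor loading in `[0, 1)`; the expected latent correlation
#'   between two features sharing a factor is `lambda^2` (at `noise_sd = 1`).
#' @param module_size_range integer `(min, max)` metabolite module sizes;
#'   min must be >= 3.
#' @param microbiome_prevalence per-feature presence probability in `(0, 1]`;
#'   absences are planted after the abundance draw, then samples are
#'   renormalized (compositional closure).
#' @param noise_sd scale of the feature-specific residual; at 1, loaded
#'   features have unit latent variance `lambda^2 + (1 - lambda^2)`.
#' @param disease_effect log-odds per standard deviation of each driver
#'   biomarker in the logistic label model.
#' @param seed RNG seed; identical configs with identical seeds give
#'   byte-identical cohorts.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 138,
                          n_mgs = 100,
                          n_metabolites = 150,
                          n_biomarkers = 30,
                          n_factors = 10,
                          lambda = 0.8,
                          module_size_range = c(5, 20),
                          microbiome_prevalence = 0.9,
                          noise_sd = 1,
                          disease_effect = 1,
                          seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_mgs = as.integer(n_mgs),
              n_metabolites = as.integer(n_metabolites),
              n_biomarkers = as.integer(n_biomarkers),
              n_factors = as.integer(n_factors), lambda = lambda,
              module_size_range = as.integer(module_size_range),
              microbiome_prevalence = microbiome_prevalence,
              noise_sd = noise_sd, disease_effect = disease_effect,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_samples, n_mgs, n_metabolites, n_biomarkers, n_factors) < 1L))
      stop("all counts must be >= 1")
    if (!is.numeric(lambda) || lambda < 0 || lambda >= 1)
      stop("lambda must be in [0, 1)")
    if (length(module_size_range) != 2L || module_size_range[1] < 3L ||
        module_size_range[2] < module_size_range[1])
      stop("module_size_range must be (min, max) with min >= 3")
    if (microbiome_prevalence <= 0 || microbiome_prevalence > 1)
      stop("microbiome_prevalence must be in (0, 1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (n_factors * module_size_range[1] > n_metabolites)
      stop("module_size_range infeasible for n_metabolites: ",
           n_factors, " modules of >= ", module_size_range[1],
           " metabolites need more than ", n_metabolites, " features")
  })
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic three-domain cohort with planted structure
#'
#' Latent-factor Gaussian model: per sample, `n_factors` independent standard
#' normal factors are drawn; a feature assigned to factor `j` has latent value
#' `lambda * f_j + sqrt(1 - lambda^2) * noise_sd * eps`, an unassigned feature
#' is pure noise. Microbiome and metabolite latents are exponentiated for
#' positivity; microbiome features receive Bernoulli zero-inflation at the
#' configured prevalence and each sample is renormalized to sum to one;
#' biomarkers are affine transforms of their latents. The binary label
#' follows a logistic model on standardized driver biomarkers that do not
#' load on any factor (case fraction calibrated to roughly 0.74 at zero
#' effect, emulating a screening cohort enriched for cases).
#'
#' @param config a [cohort_config()].
#' @return list with elements `mgs`, `metabolites`, `phenotypes` (each an
#'   [omics_matrix()]; `phenotypes` contains the biomarkers plus a 0/1
#'   `disease` column) and `truth`, a `ground_truth` list with
#'   `factor_loadings` (data.frame feature/domain/factor/lambda),
#'   `metabolite_modules` (named vector feature -> planted module id),
#'   `planted_edges` (data.frame of cross-domain pairs sharing a factor) and
#'   `disease_drivers` (data.frame feature/effect).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  K <- config$n_factors
  lam <- config$lambda
  res_sd <- sqrt(1 - lam^2) * config$noise_sd

  sample_ids <- sprintf("S%03d", seq_len(n))
  mgs_ids <- sprintf("MGS%04d", seq_len(config$n_mgs))
  met_ids <- sprintf("met%05d", seq_len(config$n_metabolites))
  bio_ids <- sprintf("BIO%03d", seq_len(config$n_biomarkers))

  F <- matrix(rnorm(n * K), n, K)

  # factor assignment: half the MGS round-robin over factors; one metabolite
  # module per factor with size drawn from the configured range; one loaded
  # biomarker per factor (while biomarkers remain)
  mgs_factor <- rep(NA_integer_, config$n_mgs)
  n_loaded_mgs <- floor(config$n_mgs / 2)
  if (n_loaded_mgs > 0L)
    mgs_factor[seq_len(n_loaded_mgs)] <- rep_len(seq_len(K), n_loaded_mgs)

  smin <- config$module_size_range[1]; smax <- config$module_size_range[2]
  sizes <- sample(seq(smin, smax), K, replace = TRUE)
  # cap so modules fit into the metabolite pool (feasibility checked in config)
  while (sum(sizes) > config$n_metabolites) {
    i <- which.max(sizes)
    sizes[i] <- max(smin, sizes[i] - (sum(sizes) - config$n_metabolites))
  }
  met_factor <- rep(NA_integer_, config$n_metabolites)
  met_factor[seq_len(sum(sizes))] <- rep(seq_len(K), times = sizes)

  bio_factor <- rep(NA_integer_, config$n_biomarkers)
  n_loaded_bio <- min(K, floor(config$n_biomarkers / 2))
  if (n_loaded_bio > 0L) bio_factor[seq_len(n_loaded_bio)] <- seq_len(n_loaded_bio)

  latent <- function(fac_of) {
    Z <- matrix(rnorm(n * length(fac_of), sd = config$noise_sd), n, length(fac_of))
    loaded <- which(!is.na(fac_of))
    if (length(loaded) > 0L) {
      E <- matrix(rnorm(n * length(loaded), sd = res_sd), n, length(loaded))
      Z[, loaded] <- lam * F[, fac_of[loaded], drop = FALSE] + E
    }
    Z
  }

  # microbiome: log-normal abundance, zero-inflation, compositional closure
  z_mgs <- latent(mgs_factor)
  base_mgs <- rnorm(config$n_mgs, mean = 0, sd = 2)
  ab <- exp(sweep(2 * z_mgs, 2, base_mgs, "+"))
  present <- matrix(rbinom(n * config$n_mgs, 1L, config$microbiome_prevalence),
                    n, config$n_mgs)
  ab <- ab * present
  dead <- rowSums(ab) == 0
  if (any(dead)) { # keep each sample's dominant feature so closure is defined
    for (i in which(dead)) {
      j <- which.max(z_mgs[i, ])
      ab[i, j] <- exp(2 * z_mgs[i, j] + base_mgs[j])
    }
  }
  mgs <- ab / rowSums(ab)
  dimnames(mgs) <- list(sample_ids, mgs_ids)

  # metabolites: log-normal intensities
  z_met <- latent(met_factor)
  base_met <- rnorm(config$n_metabolites, mean = 6, sd = 1)
  met <- exp(sweep(z_met, 2, base_met, "+"))
  dimnames(met) <- list(sample_ids, met_ids)

  # biomarkers: affine transforms of latents, clinical-looking scales
  z_bio <- latent(bio_factor)
  scale_bio <- runif(config$n_biomarkers, 1, 10)
  shift_bio <- runif(config$n_biomarkers, 10, 100)
  bio <- sweep(sweep(z_bio, 2, scale_bio, "*"), 2, shift_bio, "+")
  dimnames(bio) <- list(sample_ids, bio_ids)

  # disease label: logistic on standardized driver biomarkers chosen among the
  # factor-independent ones (microbiome carries no label signal by design)
  free_bio <- which(is.na(bio_factor))
  drivers <- free_bio[seq_len(min(5L, length(free_bio)))]
  eta <- rep(qlogis(0.74), n)
  if (length(drivers) > 0L && config$disease_effect != 0)
    eta <- eta + scale(z_bio[, drivers, drop = FALSE]) %*%
      rep(config$disease_effect, length(drivers))
  disease <- rbinom(n, 1L, plogis(drop(eta)))
  phen <- cbind(bio, disease = disease)

  module_ids <- sprintf("ME%d", seq_len(K))
  met_modules <- setNames(module_ids[met_factor[!is.na(met_factor)]],
                          met_ids[!is.na(met_factor)])

  loadings <- rbind(
    data.frame(feature = mgs_ids, domain = "microbiome_mgs", factor = mgs_factor),
    data.frame(feature = met_ids, domain = "metabolite", factor = met_factor),
    data.frame(feature = bio_ids, domain = "phenotype", factor = bio_factor))
  loadings <- loadings[!is.na(loadings$factor), ]
  loadings$lambda <- lam
  rownames(loadings) <- NULL

  planted <- do.call(rbind, lapply(seq_len(K), function(j) {
    f <- loadings[loadings$factor == j, ]
    if (nrow(f) < 2L) return(NULL)
    idx <- combn(nrow(f), 2L)
    out <- data.frame(feature_a = f$feature[idx[1, ]], domain_a = f$domain[idx[1, ]],
                      feature_b = f$feature[idx[2, ]], domain_b = f$domain[idx[2, ]],
                      factor = j)
    out[out$domain_a != out$domain_b, ]
  }))
  rownames(planted) <- NULL

  truth <- structure(list(
    factor_loadings = loadings,
    metabolite_modules = met_modules,
    planted_edges = planted,
    disease_drivers = data.frame(feature = bio_ids[drivers],
                                 effect = rep(config$disease_effect, length(drivers)))
  ), class = "ground_truth")

  list(mgs = omics_matrix(mgs, "microbiome_mgs"),
       metabolites = omics_matrix(met, "metabolite"),
       phenotypes = omics_matrix(phen, "phenotype"),
       truth = truth)
}

#' Score recovery of planted structure
#'
#' Compares inferred cross-domain edges and metabolite module assignments
#' against the generator's ground truth.
#'
#' @param truth `ground_truth` from [generate_cohort()].
#' @param inferred_edges data.frame with columns `feature_a`, `feature_b`
#'   (e.g. from [filter_for_network()]); order within a pair is ignored. May
#'   be `NULL` to skip edge scoring.
#' @param inferred_modules named vector feature -> module label (e.g. from
#'   [cluster_modules()]); may be `NULL` to skip module scoring.
#' @return list with `edge_sensitivity` (recovered planted edges / planted
#'   edges), `edge_precision`, and `module_ari` (adjusted Rand index between
#'   true and inferred labels on the features assigned in truth).
#' @export
score_recovery <- function(truth, inferred_edges = NULL, inferred_modules = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(edge_sensitivity = NA_real_, edge_precision = NA_real_,
              module_ari = NA_real_)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (!is.null(inferred_edges)) {
    truth_feats <- unique(c(truth$planted_edges$feature_a, truth$planted_edges$feature_b,
                            truth$factor_loadings$feature))
    inf_feats <- unique(c(inferred_edges$feature_a, inferred_edges$feature_b))
    if (nrow(inferred_edges) > 0L && length(intersect(inf_feats, truth_feats)) == 0L)
      stop("inferred edges share no features with the ground truth universe")
    pk <- key(truth$planted_edges$feature_a, truth$planted_edges$feature_b)
    ik <- unique(key(inferred_edges$feature_a, inferred_edges$feature_b))
    out$edge_sensitivity <- if (length(pk) > 0L) mean(pk %in% ik) else NA_real_
    out$edge_precision <- if (length(ik) > 0L) mean(ik %in% pk) else NA_real_
  }
  if (!is.null(inferred_modules)) {
    feats <- names(truth$metabolite_modules)
    if (length(intersect(feats, names(inferred_modules))) == 0L)
      stop("inferred modules share no features with the ground truth universe")
    inf <- inferred_modules[feats]
    inf[is.na(inf)] <- "unassigned"
    out$module_ari <- mclust::adjustedRandIndex(truth$metabolite_modules, inf)
  }
  out
}

#' Write a cohort to disk
#'
#' Three TSV matrices (features x samples, see [write_omics_matrix()]) plus
#' the ground truth as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(cohort$mgs, file.path(outdir, "mgs.tsv"))
  write_omics_matrix(cohort$metabolites, file.path(outdir, "metabolites.tsv"))
  write_omics_matrix(cohort$phenotypes, file.path(outdir, "phenotypes.tsv"))
  jsonlite::write_json(lapply(unclass(cohort$truth), function(x) {
    if (is.vector(x) && !is.null(names(x)) && !is.data.frame(x)) as.list(x) else x
  }), file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
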
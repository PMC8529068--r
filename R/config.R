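#' Analysis configuration
#'
#' All tunable thresholds of the pipeline in one validated object. The
#' defaults are the values used throughout the analysis: Spearman retention at
#' p < 0.05, Benjamini-Hochberg q < 0.1, network edge filter |rho| >= 0.3,
#' soft threshold beta = 13 chosen on a 1..20 grid by the scale-free topology
#' criterion, dynamic tree cut with deep split 4 and minimum module size 3,
#' reporter significance at |Z| >= 1.96, 10-fold cross-validation repeated 5
#' times, 999 PERMANOVA permutations, and a strict >10% prevalence filter.
#'
#' @param p_threshold two-sided p-value cutoff for triangular retention.
#' @param q_threshold BH-adjusted q cutoff for network edges.
#' @param rho_min minimum |Spearman rho| for network edges (boundary kept).
#' @param beta soft-threshold power for the signed metabolite network.
#' @param beta_grid candidate powers scanned by [pick_soft_threshold()].
#' @param r2_target scale-free fit R-squared target for the beta scan.
#' @param deep_split tree-cut sensitivity, integer 0..4 (higher = finer).
#' @param min_module_size smallest allowed metabolite module.
#' @param z_threshold reporter-score significance cutoff.
#' @param cv_folds,cv_repeats cross-validation scheme.
#' @param n_perm PERMANOVA permutation count.
#' @param prevalence_min strict fraction-of-samples cutoff for MGS features.
#' @param min_community_size communities below this size are pruned from
#'   summaries.
#' @param seed master seed fanned out to all stochastic stages.
#' @return object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(p_threshold = 0.05,
                            q_threshold = 0.1,
                            rho_min = 0.3,
                            beta = 13,
                            beta_grid = 1:20,
                            r2_target = 0.85,
                            deep_split = 4,
                            min_module_size = 3,
                            z_threshold = 1.96,
                            cv_folds = 10,
                            cv_repeats = 5,
                            n_perm = 999,
                            prevalence_min = 0.10,
                            min_community_size = 5,
                            seed = 1) {
  cfg <- list(p_threshold = p_threshold, q_threshold = q_threshold,
              rho_min = rho_min, beta = beta, beta_grid = beta_grid,
              r2_target = r2_target, deep_split = deep_split,
              min_module_size = min_module_size, z_threshold = z_threshold,
              cv_folds = cv_folds, cv_repeats = cv_repeats, n_perm = n_perm,
              prevalence_min = prevalence_min,
              min_community_size = min_community_size, seed = seed)
  .validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

.validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x <= 1
  if (!in01(cfg$p_threshold)) stop("p_threshold must be in (0, 1]")
  if (!in01(cfg$q_threshold)) stop("q_threshold must be in (0, 1]")
  if (!is.numeric(cfg$rho_min) || cfg$rho_min < 0 || cfg$rho_min > 1)
    stop("rho_min must be in [0, 1]")
  if (!is.numeric(cfg$beta) || cfg$beta <= 0) stop("beta must be > 0")
  if (length(cfg$beta_grid) < 1L || any(cfg$beta_grid <= 0))
    stop("beta_grid must be a non-empty set of positive powers")
  if (!cfg$deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  if (cfg$min_module_size < 3) stop("min_module_size must be >= 3")
  if (cfg$z_threshold <= 0) stop("z_threshold must be > 0")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  if (cfg$cv_repeats < 1) stop("cv_repeats must be >= 1")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (!is.numeric(cfg$prevalence_min) || cfg$prevalence_min < 0 || cfg$prevalence_min >= 1)
    stop("prevalence_min must be in [0, 1)")
  if (cfg$min_community_size < 1) stop("min_community_size must be >= 1")
  if (!is.numeric(cfg$seed) || is.na(cfg$seed)) stop("seed must be an integer")
  invisible(cfg)
}

#' Load / save an analysis configuration as YAML
#'
#' An empty or absent-key YAML file yields the defaults of
#' [analysis_config()]; unknown keys are rejected; out-of-range values raise
#' a validation error. `save_config()` followed by `load_config()` is an
#' identity.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname load_config
#' @param config an `analysis_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Deterministic per-stage seed derived from the master seed, kept inside
# 32-bit integer range so set.seed() accepts it everywhere.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

#' Write a run manifest
#'
#' Records the configuration, seeds, package version and per-file MD5
#' checksums of a pipeline run; re-running with the same config and seed
#' reproduces deterministic stage outputs bit for bit.
#'
#' @param outdir results directory containing the stage outputs.
#' @param config the `analysis_config` used.
#' @param files character vector of output files to checksum.
#' @param extra optional named list merged into the manifest.
#' @return path of the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(outdir, config, files = list.files(outdir, full.names = TRUE),
                           extra = list()) {
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- c(list(
    package = "trinetomics",
    version = as.character(utils::packageVersion("trinetomics")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(files))
  ), extra)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
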
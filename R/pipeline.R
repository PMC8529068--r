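#' Run the full trans-omics analysis on three aligned matrices
#'
#' Orchestrates every stage with one configuration and one master seed:
#' prevalence filtering and diversity summaries; metabolite co-abundance
#' clustering (log2, bicor, signed adjacency at the configured beta,
#' topological overlap, tree cut) summarized by eigenprofiles; the three
#' all-pairs Spearman screens with per-screen BH control and triangular
#' retention; PERMANOVA covariate screening on Bray-Curtis distances;
#' Mann-Whitney differential abundance against the disease label (plus
#' reporter scoring when a feature-to-module map is supplied); the
#' q/|rho|-filtered inter-omic graph with Girvan-Newman communities and
#' their summaries; and repeated down-sampled cross-validated classification
#' of the disease label from biomarkers and from MGS. Stage outputs are
#' written to `outdir` as TSV/JSON together with a reproducibility manifest.
#'
#' @param mgs,metabolites,phenotypes [omics_matrix()] objects; `phenotypes`
#'   must contain the binary column named by `disease_col` plus continuous
#'   biomarkers.
#' @param config an [analysis_config()].
#' @param outdir output directory (created if needed).
#' @param feature_map optional data.frame (`feature`, `module`) mapping MGS
#'   features to functional modules for reporter scoring.
#' @param disease_col name of the binary label column in `phenotypes`.
#' @return (invisibly) a list with every stage result: `modules`,
#'   `eigenprofiles`, `edges`, `triangles`, `permanova`, `diffabund`,
#'   `reporter`, `graph`, `communities`, `summary`, `classification`,
#'   `prediction`.
#' @export
run_pipeline <- function(mgs, metabolites, phenotypes,
                         config = analysis_config(), outdir,
                         feature_map = NULL, disease_col = "disease") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  aligned <- align_samples(mgs = mgs, metabolites = metabolites,
                           phenotypes = phenotypes)
  mgs <- aligned$mgs; metabolites <- aligned$metabolites
  phenotypes <- aligned$phenotypes
  tsv <- function(df, name) write.table(df, file.path(outdir, name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)

  message("stage: preprocess")
  mgs <- prevalence_filter(mgs, config$prevalence_min)
  div <- data.frame(sample = rownames(mgs), shannon = shannon_diversity(mgs),
                    richness = richness(mgs))
  tsv(div, "diversity.tsv")

  message("stage: cluster-metabolites")
  lmet <- log2_transform(metabolites)
  cmat <- bicor_matrix(.values(lmet))
  adj <- signed_adjacency(cmat, config$beta)
  dis <- tom_dissimilarity(adj)
  partition <- cluster_modules(dis, deep_split = config$deep_split,
                               min_size = config$min_module_size,
                               data = .values(lmet))
  tsv(data.frame(feature = names(partition), module = unname(partition)),
      "metabolite_modules.tsv")
  eig <- eigenprofiles(.values(lmet), partition)
  eig_mat <- omics_matrix(eig$scores, "metabolite")
  write_omics_matrix(eig_mat, file.path(outdir, "eigenprofiles.tsv"))

  message("stage: correlate")
  disease <- .values(phenotypes)[, disease_col]
  biomarkers <- omics_matrix(
    .values(phenotypes)[, setdiff(colnames(phenotypes), disease_col), drop = FALSE],
    "phenotype")
  e_mgs_phe <- correlate_pairs(mgs, biomarkers)
  e_met_phe <- correlate_pairs(eig_mat, biomarkers)
  e_mgs_met <- correlate_pairs(mgs, eig_mat)
  edges <- rbind(e_mgs_phe, e_met_phe, e_mgs_met)
  tsv(edges, "edges.tsv")
  tri <- triangular_retention(e_mgs_phe, e_met_phe, e_mgs_met,
                              p_threshold = config$p_threshold)
  tsv(tri$triangles, "triangles.tsv")

  message("stage: permanova")
  d_bray <- bray_curtis(mgs)
  perm <- permanova_screen(d_bray, biomarkers, n_perm = config$n_perm,
                           seed = .stage_seed(config$seed, "permanova"))
  tsv(perm, "permanova.tsv")

  message("stage: diffabund")
  da <- differential_abundance(mgs, disease)
  tsv(da, "diffabund.tsv")
  rep_scores <- NULL
  if (!is.null(feature_map)) {
    fm <- feature_map[feature_map$feature %in% da$feature, , drop = FALSE]
    if (nrow(fm) > 0L) {
      rep_scores <- reporter_score(fm, setNames(da$p, da$feature),
                                   setNames(da$direction, da$feature),
                                   z_threshold = config$z_threshold,
                                   seed = .stage_seed(config$seed, "reporter"))
      tsv(rep_scores, "reporter.tsv")
    }
  }

  message("stage: network")
  net_edges <- filter_for_network(edges, q_max = config$q_threshold,
                                  rho_min = config$rho_min)
  graph <- NULL; comm <- NULL; summ <- NULL
  if (nrow(net_edges) > 0L) {
    graph <- graph_from_edges(net_edges)
    comm <- girvan_newman(graph)
    summ <- community_summary(graph, comm$membership,
                              min_size = config$min_community_size)
    tsv(data.frame(node = names(comm$membership),
                   community = unname(comm$membership)), "communities.tsv")
    if (nrow(summ$edges) > 0L) tsv(summ$edges, "community_summary.tsv")
    write_graphml(graph, file.path(outdir, "network.graphml"), comm$membership)
  } else {
    message("network: no edges pass the q/|rho| filter")
  }

  message("stage: classify/predict")
  scheme <- cv_scheme(folds = config$cv_folds, repeats = config$cv_repeats,
                      seed = .stage_seed(config$seed, "cv"))
  y <- factor(disease)
  cls <- list(biomarkers = repeated_cv(biomarkers, y, scheme),
              mgs = repeated_cv(mgs, y, scheme))
  target <- perm$variable[1L] # best-explained biomarker as regression target
  prd <- repeated_cv(mgs, .values(biomarkers)[, target], scheme)
  metrics <- list(
    classification = lapply(cls, function(z)
      list(auc = z$metric, per_repeat = z$per_repeat)),
    prediction = list(target = target, spearman = prd$metric,
                      per_repeat = prd$per_repeat))
  jsonlite::write_json(metrics, file.path(outdir, "cv_metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  write_manifest(outdir, config)
  invisible(list(mgs = mgs, modules = partition, eigenprofiles = eig,
                 edges = edges, triangles = tri, permanova = perm,
                 diffabund = da, reporter = rep_scores, graph = graph,
                 communities = comm, summary = summ,
                 classification = cls, prediction = prd))
}

#' Simulate a cohort and run the full pipeline on it
#'
#' Convenience wrapper: generates a synthetic cohort (seeded from the
#' analysis seed), runs [run_pipeline()], and scores recovery of the planted
#' structure against the generator's ground truth.
#'
#' @param config an [analysis_config()]; its seed drives the simulation.
#' @param outdir results directory.
#' @param cohort_cfg a [cohort_config()]; defaults to the standard cohort at
#'   the analysis seed.
#' @return (invisibly) the [run_pipeline()] result list, plus `cohort` and
#'   `recovery` (edge sensitivity/precision and module ARI).
#' @export
run_all <- function(config = analysis_config(), outdir,
                    cohort_cfg = cohort_config(seed = config$seed)) {
  cohort <- generate_cohort(cohort_cfg)
  fm <- with(cohort$truth, factor_loadings[factor_loadings$domain == "microbiome_mgs", ])
  feature_map <- if (nrow(fm) > 0L)
    data.frame(feature = fm$feature, module = sprintf("FM%d", fm$factor)) else NULL
  res <- run_pipeline(cohort$mgs, cohort$metabolites, cohort$phenotypes,
                      config = config, outdir = outdir,
                      feature_map = feature_map)
  # planted edges live at the metabolite *feature* level, while the pipeline
  # network uses module eigenprofiles; recovery is therefore scored on
  # feature-level screens computed directly
  feat_edges <- feature_level_edges(cohort, config, disease_col = "disease")
  recovery <- score_recovery(cohort$truth,
                             inferred_edges = feat_edges,
                             inferred_modules = res$modules)
  jsonlite::write_json(recovery, file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(cohort = cohort, recovery = recovery,
                        feature_edges = feat_edges)))
}

#' Feature-level filtered inter-omic edges of a cohort
#'
#' The three all-pairs Spearman screens on raw features (MGS x metabolite,
#' MGS x biomarker, metabolite x biomarker), each BH-adjusted within its own
#' screen, then passed through [filter_for_network()]. Used to score
#' recovery of planted feature pairs.
#'
#' @param cohort list with `mgs`, `metabolites`, `phenotypes` (e.g. from
#'   [generate_cohort()]).
#' @param config an [analysis_config()].
#' @param disease_col label column excluded from the biomarker screen.
#' @return filtered edge data.frame.
#' @export
feature_level_edges <- function(cohort, config = analysis_config(),
                                disease_col = "disease") {
  bio <- omics_matrix(
    .values(cohort$phenotypes)[, setdiff(colnames(cohort$phenotypes), disease_col),
                               drop = FALSE], "phenotype")
  edges <- rbind(correlate_pairs(cohort$mgs, cohort$metabolites),
                 correlate_pairs(cohort$mgs, bio),
                 correlate_pairs(cohort$metabolites, bio))
  filter_for_network(edges, q_max = config$q_threshold, rho_min = config$rho_min)
}
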
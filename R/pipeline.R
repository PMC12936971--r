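# Workflow orchestration: simulate -> msn -> topology -> normative ->
# deviations -> fuse -> cluster -> decode -> report, with per-stage derived
# seeds, cached intermediates, text-file outputs, and a checksum manifest.

#' Pipeline configuration
#'
#' Collects every stage's parameters around one master seed. Per-stage seeds
#' are derived by hashing the master seed with the stage name, so optional
#' stages can be added or dropped without disturbing other stages' random
#' streams.
#'
#' @param spec A [cohort_spec()]; its `seed` is overridden by a seed derived
#'   from `master_seed`.
#' @param master_seed Master integer seed.
#' @param sparsity Retained edge fraction for network thresholding.
#' @param n_bins Bins for density estimation.
#' @param density_method Density estimator for MSN construction: `"kde"`
#'   (default; robust at a few hundred samples per region) or
#'   `"histogram"`.
#' @param k_grid Candidate biotype counts.
#' @param n_restarts HYDRA restarts.
#' @param n_folds Cross-validation folds for selecting k.
#' @param C HYDRA regularization constant.
#' @param n_perm Group-permutation count.
#' @param n_surrogates Spin surrogates.
#' @param n_annotations,annotation_smoothness Synthetic annotation maps used
#'   by the decode stage.
#' @param n_terms Synthetic cognitive-term maps for PLS decoding.
#' @param n_boot Bootstrap resamples for PLS term loadings.
#' @param variance_floor Explained-variance floor for fusion component count.
#' @param permute_within_site Shuffle group labels within site in the group
#'   permutation test (default TRUE).
#' @param stage_list Ordered subset of stages to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(n_controls = 300L,
                                               n_cases = 200L),
                            master_seed = 1L, sparsity = 0.3,
                            n_bins = 128L, density_method = c("kde", "histogram"),
                            k_grid = 2:4, n_restarts = 5L,
                            n_folds = 10L, C = 0.25, n_perm = 1000L,
                            n_surrogates = 1000L, n_annotations = 19L,
                            annotation_smoothness = 0.5, n_terms = 25L,
                            n_boot = 500L, variance_floor = 0.8,
                            permute_within_site = TRUE,
                            stage_list = c("simulate", "msn", "topology",
                                           "normative", "deviations", "fuse",
                                           "cluster", "decode", "report")) {
  density_method <- match.arg(density_method)
  spec$seed <- derive_seed(master_seed, "simulate")
  structure(list(spec = spec, master_seed = as.integer(master_seed),
                 sparsity = sparsity, n_bins = as.integer(n_bins),
                 density_method = density_method,
                 k_grid = as.integer(k_grid),
                 n_restarts = as.integer(n_restarts),
                 n_folds = as.integer(n_folds), C = C,
                 n_perm = as.integer(n_perm),
                 n_surrogates = as.integer(n_surrogates),
                 n_annotations = as.integer(n_annotations),
                 annotation_smoothness = annotation_smoothness,
                 n_terms = as.integer(n_terms), n_boot = as.integer(n_boot),
                 variance_floor = variance_floor,
                 permute_within_site = permute_within_site,
                 stage_list = stage_list),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$spec <- unclass(cfg$spec)
  cfg$stage_list <- NULL   # which stages run is not semantic for outputs
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

flatten_deviations <- function(devs) {
  dims <- dim(devs$z)
  metrics <- dimnames(devs$z)[[3]]
  X <- matrix(devs$z, dims[1], dims[2] * dims[3])
  colnames(X) <- as.vector(outer(sprintf("node%03d", seq_len(dims[2])),
                                 metrics, paste, sep = "_"))
  X
}

stage_seed <- function(config, stage) derive_seed(config$master_seed, stage)

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order. Each stage caches its state under
#' `workspace/cache/<stage>.rds` and writes its tables as TSV/JSON under
#' `workspace/<stage>/`. A stage is recomputed when its cache is missing, the
#' configuration hash changed, or an upstream stage was recomputed — so
#' deleting one intermediate recomputes only that stage and everything
#' downstream. The manifest (config hash, per-stage output checksums,
#' package version) is written to `workspace/manifest.json`; stage timings go
#' to a separate `timings.json` so manifests of identical runs are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param workspace Directory for caches, outputs, manifest.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `manifest`, `state` (in-memory stage
#'   results), and `ran` (which stages were recomputed).
#' @export
run_pipeline <- function(config, workspace, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(workspace, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  chash <- config_hash(config)
  hash_file <- file.path(workspace, "config_hash")
  stale <- !file.exists(hash_file) || readLines(hash_file)[1] != chash
  writeLines(chash, hash_file)

  state <- new.env(parent = emptyenv())
  manifest <- list(config_hash = chash,
                   package_version = as.character(
                     utils::packageVersion("msnbiotypes")),
                   stages = list())
  ran <- character(0)
  timings <- list()
  upstream_ran <- stale

  for (stage in config$stage_list) {
    cache <- file.path(workspace, "cache", paste0(stage, ".rds"))
    outdir <- file.path(workspace, stage)
    t0 <- Sys.time()
    if (!upstream_ran && file.exists(cache)) {
      res <- readRDS(cache)
      for (nm in names(res$state)) assign(nm, res$state[[nm]], envir = state)
    } else {
      if (!quiet) message("running stage: ", stage)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      res <- run_stage(stage, config, state, outdir)
      for (nm in names(res$state)) assign(nm, res$state[[nm]], envir = state)
      saveRDS(res, cache, compress = FALSE)
      ran <- c(ran, stage)
      upstream_ran <- TRUE
    }
    timings[[stage]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    sums <- tools::md5sum(sort(res$outputs))
    manifest$stages[[stage]] <- list(
      outputs = as.list(stats::setNames(unname(sums), basename(res$outputs))))
  }
  write_json(manifest, file.path(workspace, "manifest.json"))
  write_json(timings, file.path(workspace, "timings.json"))
  invisible(list(manifest = manifest, state = as.list(state), ran = ran))
}

run_stage <- function(stage, config, state, outdir) {
  switch(stage,
    simulate = stage_simulate(config, state, outdir),
    msn = stage_msn(config, state, outdir),
    topology = stage_topology(config, state, outdir),
    normative = stage_normative(config, state, outdir),
    deviations = stage_deviations(config, state, outdir),
    fuse = stage_fuse(config, state, outdir),
    cluster = stage_cluster(config, state, outdir),
    decode = stage_decode(config, state, outdir),
    report = stage_report(config, state, outdir),
    stop(sprintf("stage %s failed: unknown stage", stage)))
}

stage_simulate <- function(config, state, outdir) {
  sim <- generate_cohort(config$spec)
  f_cohort <- file.path(outdir, "cohort.tsv")
  write_tsv(sim$cohort, f_cohort)
  geo <- sim$geometry
  geo$region_index <- geo$region_index - 1L          # 0-based on disk
  f_geo <- file.path(outdir, "geometry.tsv")
  write_tsv(geo, f_geo)
  f_gt <- file.path(outdir, "ground_truth.json")
  write_json(list(biotype_nodes = lapply(sim$ground_truth$biotype_nodes,
                                         function(v) v - 1L),
                  modules = sim$ground_truth$modules,
                  decoupling_weight = sim$ground_truth$decoupling_weight), f_gt)
  list(state = list(sim = sim), outputs = c(f_cohort, f_geo, f_gt))
}

stage_msn <- function(config, state, outdir) {
  msns <- build_msn_batch(state$sim$samples, n_bins = config$n_bins,
                          method = config$density_method)
  mean_edge <- vapply(msns, function(m) mean(m[upper.tri(m)]), numeric(1))
  f <- file.path(outdir, "msn_summary.tsv")
  write_tsv(data.frame(subject_id = names(msns), mean_edge = mean_edge), f)
  list(state = list(msns = msns), outputs = f)
}

stage_topology <- function(config, state, outdir) {
  cohort <- state$sim$cohort
  ctrl <- cohort$group == "control"
  ctrl_graphs <- lapply(state$msns[ctrl], function(m)
    threshold_network(m, config$sparsity)$adjacency)
  partition <- consensus_partition(ctrl_graphs,
                                   seed = stage_seed(config, "topology"))
  topo <- topology_profile_batch(state$msns, partition, config$sparsity)
  f_part <- file.path(outdir, "partition.json")
  write_json(list(partition = partition, sparsity = config$sparsity), f_part)
  long <- data.frame(
    subject_id = rep(dimnames(topo)[[1]], times = dim(topo)[2] * 3),
    region_index = rep(rep(seq_len(dim(topo)[2]) - 1L,
                           each = dim(topo)[1]), 3),
    metric = rep(dimnames(topo)[[3]], each = dim(topo)[1] * dim(topo)[2]),
    value = as.vector(topo))
  f_topo <- file.path(outdir, "topology.tsv")
  write_tsv(long, f_topo)
  list(state = list(partition = partition, topo = topo),
       outputs = c(f_part, f_topo))
}

stage_normative <- function(config, state, outdir) {
  cohort <- state$sim$cohort
  ctrl <- cohort$group == "control"
  models <- fit_normative_batch(state$topo[ctrl, , , drop = FALSE],
                                cohort$age[ctrl], cohort$sex[ctrl])
  devs <- deviation_tensor(models, state$topo, cohort$age, cohort$sex)
  site_acc <- check_site_effects(flatten_deviations(devs), cohort$site,
                                 seed = stage_seed(config, "sitecheck"))
  f_site <- file.path(outdir, "site_check.json")
  write_json(list(balanced_accuracy = site_acc,
                  chance = 1 / length(unique(cohort$site))), f_site)
  X <- flatten_deviations(devs)
  f_dev <- file.path(outdir, "deviations.tsv")
  write_tsv(data.frame(subject_id = cohort$subject_id, round(X, 6)), f_dev)
  list(state = list(models = models, devs = devs, site_acc = site_acc),
       outputs = c(f_site, f_dev))
}

stage_deviations <- function(config, state, outdir) {
  cohort <- state$sim$cohort
  devs <- state$devs
  is_case <- cohort$group == "case"
  metrics <- dimnames(devs$z)[[3]]
  geometry <- state$sim$geometry
  perms <- spin_permutations(geometry, config$n_surrogates,
                             stage_seed(config, "spin"))
  site <- if (config$permute_within_site) cohort$site else NULL
  maps <- list(); tabs <- list()
  for (m in metrics) {
    case_map <- overlap_map(devs, is_case, m)
    ctrl_map <- overlap_map(devs, !is_case, m)
    gp <- group_permutation_test(devs, is_case, m, n_perm = config$n_perm,
                                 seed = stage_seed(config, paste0("gp_", m)),
                                 site = site)
    sp <- spin_test(case_map, ctrl_map, geometry, stat = "difference",
                    perms = perms)
    q <- fdr_bh(gp$p)$q
    tabs[[m]] <- data.frame(region_index = geometry$region_index - 1L,
                            metric = m, case_prop = case_map,
                            control_prop = ctrl_map,
                            difference = gp$observed,
                            p_group = gp$p, p_spin = sp$p, q = q,
                            cohen_h = cohen_h(case_map, ctrl_map))
    maps[[m]] <- gp$observed
  }
  tab <- do.call(rbind, tabs)
  f_maps <- file.path(outdir, "difference_maps.tsv")
  write_tsv(tab, f_maps)
  burden <- extreme_burden_compare(devs, is_case)
  f_burden <- file.path(outdir, "extreme_burden.tsv")
  write_tsv(burden, f_burden)
  sig <- tab[tab$q < 0.05, c("region_index", "metric", "difference", "q")]
  f_sig <- file.path(outdir, "significant_nodes.json")
  write_json(sig, f_sig)
  list(state = list(diff_maps = maps, diff_table = tab, burden = burden),
       outputs = c(f_maps, f_burden, f_sig))
}

stage_fuse <- function(config, state, outdir) {
  cohort <- state$sim$cohort
  devs <- state$devs
  metrics <- dimnames(devs$z)[[3]]
  X_k <- lapply(seq_along(metrics), function(m) devs$z[, , m])
  sel <- select_component_count(X_k, config$variance_floor)
  fus <- mcca_jica(X_k, sel$n_components,
                   seed = stage_seed(config, "fuse"))
  gt <- component_group_test(fus$A_k, cohort$group == "case")
  f_ev <- file.path(outdir, "explained_variance.tsv")
  write_tsv(data.frame(metric = rep(metrics, each = ncol(sel$explained_variance)),
                       components = rep(seq_len(ncol(sel$explained_variance)),
                                        length(metrics)),
                       explained = as.vector(t(sel$explained_variance))), f_ev)
  f_gt <- file.path(outdir, "component_tests.tsv")
  write_tsv(gt$table, f_gt)
  f_joint <- file.path(outdir, "joint_components.json")
  write_json(list(n_components = sel$n_components,
                  joint = which(gt$joint)), f_joint)
  list(state = list(fusion = fus, fusion_tests = gt,
                    n_components = sel$n_components),
       outputs = c(f_ev, f_gt, f_joint))
}

stage_cluster <- function(config, state, outdir) {
  cohort <- state$sim$cohort
  is_case <- cohort$group == "case"
  X <- flatten_deviations(state$devs)
  cv <- cv_select_k(X, is_case, k_grid = config$k_grid,
                    n_folds = config$n_folds,
                    seed = stage_seed(config, "cluster"),
                    n_restarts = config$n_restarts, C = config$C)
  model <- cv$full_models[[paste0("k", cv$chosen_k)]]
  labels <- rep(NA_integer_, nrow(X))
  labels[is_case] <- model$case_labels
  f_model <- file.path(outdir, "hydra_model.json")
  save_hydra(model, f_model)
  f_assign <- file.path(outdir, "assignments.tsv")
  write_tsv(data.frame(subject_id = cohort$subject_id[is_case],
                       biotype = model$case_labels), f_assign)
  kw <- lapply(c(inattention = "inattention", hyperactivity = "hyperactivity"),
               function(sc) kruskal_wallis(cohort[[sc]][is_case],
                                           model$case_labels))
  ph <- lapply(c(inattention = "inattention", hyperactivity = "hyperactivity"),
               function(sc) posthoc_pairwise(cohort[[sc]][is_case],
                                             model$case_labels))
  f_clin <- file.path(outdir, "clinical_profiles.json")
  write_json(list(kruskal_wallis = kw,
                  posthoc = lapply(ph, function(d)
                    stats::setNames(as.list(d$adjusted_p), d$pair)),
                  cv_ari = as.list(cv$ari), chosen_k = cv$chosen_k), f_clin)
  chisq <- do.call(rbind, lapply(dimnames(state$devs$z)[[3]], function(m) {
    d <- suppressWarnings(biotype_node_chisq(state$devs, labels, m))
    d$metric <- m; d
  }))
  f_chi <- file.path(outdir, "biotype_node_chisq.tsv")
  write_tsv(chisq, f_chi)
  list(state = list(hydra = model, cv = cv, biotype_labels = labels,
                    clinical = list(kw = kw, posthoc = ph)),
       outputs = c(f_model, f_assign, f_clin, f_chi))
}

stage_decode <- function(config, state, outdir) {
  geometry <- state$sim$geometry
  fused <- fuse_maps(state$diff_maps)
  ann <- generate_annotation_maps(geometry, config$n_annotations,
                                  config$annotation_smoothness,
                                  seed = stage_seed(config, "annotations"))
  corr <- annotation_correlation(fused, ann, geometry,
                                 n_surrogates = config$n_surrogates,
                                 seed = stage_seed(config, "spin_ann"))
  terms <- generate_annotation_maps(geometry, config$n_terms,
                                    config$annotation_smoothness,
                                    seed = stage_seed(config, "terms"))
  term_mat <- as.matrix(terms[, -1])
  pls <- pls_decode(fused, term_mat, geometry, n_boot = config$n_boot,
                    n_surrogates = config$n_surrogates,
                    seed = stage_seed(config, "pls"))
  f_fused <- file.path(outdir, "fused_map.tsv")
  write_tsv(data.frame(region_index = geometry$region_index - 1L,
                       fused = fused), f_fused)
  f_corr <- file.path(outdir, "annotation_correlations.tsv")
  write_tsv(corr, f_corr)
  f_pls <- file.path(outdir, "pls_terms.tsv")
  write_tsv(pls$terms, f_pls)
  f_sum <- file.path(outdir, "pls_summary.json")
  write_json(list(explained_variance = pls$explained_variance,
                  p_spin = pls$p_spin,
                  orientation = "terms as predictors, fused map as response"),
             f_sum)
  list(state = list(fused = fused, annotation_corr = corr, pls = pls),
       outputs = c(f_fused, f_corr, f_pls, f_sum))
}

stage_report <- function(config, state, outdir) {
  lines <- c(
    "# Pipeline report", "",
    sprintf("- subjects: %d controls / %d cases, %d regions, %d sites",
            config$spec$n_controls, config$spec$n_cases,
            config$spec$n_regions, config$spec$n_sites),
    sprintf("- site-prediction balanced accuracy: %.3f (chance %.3f)",
            state$site_acc, 1 / config$spec$n_sites),
    sprintf("- fusion components: %d; joint group-differentiating: %s",
            state$n_components,
            paste(which(state$fusion_tests$joint), collapse = ", ")),
    sprintf("- chosen k: %d (CV ARI: %s)", state$cv$chosen_k,
            paste(sprintf("%s=%.3f", names(state$cv$ari), state$cv$ari),
                  collapse = ", ")),
    sprintf("- biotype sizes: %s",
            paste(table(state$hydra$case_labels), collapse = ", ")),
    sprintf("- PLS explained variance: %.3f (spin p = %.4f)",
            state$pls$explained_variance, state$pls$p_spin))
  f <- file.path(outdir, "report.md")
  writeLines(lines, f)
  list(state = list(), outputs = f)
}

#' Transfer a pretrained pipeline to a validation cohort
#'
#' Applies identical processing to a new cohort (MSN construction, topology
#' with the pretrained partition and sparsity), recalibrates the pretrained
#' normative models with the validation cohort's controls, scores deviations,
#' and assigns validation cases to biotypes by maximum expression score
#' against the pretrained polytope. Reports biotype sizes, clinical
#' contrasts, and between-cohort correlations of per-biotype mean deviation
#' vectors.
#'
#' @param pretrained List with `hydra`, `models` (normative model set),
#'   `partition`, `sparsity`, `n_bins`, `density_method`, and `train` (list
#'   with `X` deviations matrix and `labels` for the training cases).
#' @param validation A cohort list as returned by [generate_cohort()].
#' @return List with `assignment`, `biotype_sizes`, `clinical`
#'   (Kruskal-Wallis on symptoms across assigned biotypes), `profile_cor`
#'   (per-biotype correlation of mean deviation vectors across cohorts), and
#'   `devs`.
#' @export
transfer_validate <- function(pretrained, validation) {
  cohort <- validation$cohort
  method <- pretrained$density_method
  if (is.null(method)) method <- "histogram"
  msns <- build_msn_batch(validation$samples, n_bins = pretrained$n_bins,
                          method = method)
  topo <- topology_profile_batch(msns, pretrained$partition,
                                 pretrained$sparsity)
  ctrl <- cohort$group == "control"
  if (!any(ctrl)) stop("validation cohort has no adaptation controls")
  models <- transfer_recalibrate_batch(pretrained$models,
                                       topo[ctrl, , , drop = FALSE],
                                       cohort$age[ctrl], cohort$sex[ctrl],
                                       site = "validation")
  devs <- deviation_tensor(models, topo, cohort$age, cohort$sex)
  X <- flatten_deviations(devs)
  is_case <- cohort$group == "case"
  es <- expression_scores(pretrained$hydra, X[is_case, , drop = FALSE])
  assignment <- es$assignment
  k <- pretrained$hydra$k
  profile_cor <- vapply(seq_len(k), function(j) {
    va <- colMeans(X[is_case, , drop = FALSE][assignment == j, ,
                                              drop = FALSE])
    tr <- colMeans(pretrained$train$X[pretrained$train$labels == j, ,
                                      drop = FALSE])
    stats::cor(va, tr)
  }, numeric(1))
  clinical <- if (length(unique(assignment)) > 1) {
    lapply(c(inattention = "inattention",
             hyperactivity = "hyperactivity"), function(sc)
      kruskal_wallis(cohort[[sc]][is_case], assignment))
  } else {
    warning("all validation cases assigned to one biotype; skipping clinical contrasts")
    NULL
  }
  list(assignment = assignment,
       biotype_sizes = as.integer(table(factor(assignment, levels = 1:k))),
       clinical = clinical, profile_cor = profile_cor, devs = devs,
       scores = es$scores)
}
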
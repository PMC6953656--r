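#' Structured run configuration for the analysis pipeline
#'
#' Collects every tunable of the end-to-end chain — synthetic-world
#' dimensions, Markov-clustering parameters, community filters, permutation
#' counts — with one explicit top-level seed (no wall-clock defaults). Each
#' stage derives its own seed by a fixed rule
#' (`(seed mod 1e6) * 1000 + stage index`) so stages are independently
#' reproducible. The defaults describe the packaged validation scenario: a
#' 24 x 24-pixel world, 40 species, 20,000 records, with clustering and
#' filter thresholds scaled to that data volume.
#'
#' @param out_dir output directory (created if needed).
#' @param seed top-level integer seed.
#' @param ... named overrides of any default listed in the function body
#'   (nested lists merged shallowly per section).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    world = list(extent = c(0, 12, 40, 52), grid_shape = c(24, 24),
                 n_env_vars = 5, n_classes = 6, n_climes = 3,
                 n_species = 40, n_records = 20000, effort_ratio = 10),
    mcl = list(inflation = 2, pre_inflation = 1, expansion = 2,
               edge_radius = 0.75, kernel_bandwidth = 0.5,
               prune_threshold = 1e-5, max_iter = 100,
               convergence_tol = 1e-6, snap = 0.25),
    boundary_rule = "cell",
    filters = list(min_sites_per_species = 5, min_obs_per_site = 50),
    dissimilarity = list(variant = "horn"),
    mrm = list(n_perm = 199,
               climate_vars = c("temp_like", "precip_like"),
               vegetation_vars = c("treecover_like", "herb_like"),
               elevation_var = "elev_like"),
    gdm = list(n_splines = 3, n_perm = 49, alpha = 0.05))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()] object.
#' @param path YAML file path.
#' @return `path` invisibly; `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

stage_order <- c("simulate", "sites", "extract", "dissim", "mrm", "gdm", "map")

stage_seed <- function(config, stage) {
  (config$seed %% 1000000L) * 1000L + match(stage, stage_order)
}

art <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(config, file, producer) {
  p <- art(config, file)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run %s first", file, producer))
  p
}

manifest_append <- function(config, stage, inputs, outputs, counts = list()) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  entry <- list(stage = stage,
                seed = stage_seed(config, stage),
                config_hash = unname(tools::md5sum(cfg_file)),
                inputs = as.list(tools::md5sum(inputs)),
                outputs = as.list(tools::md5sum(outputs)),
                counts = counts)
  unlink(cfg_file)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE),
      file = art(config, "manifest.jsonl"), sep = "\n", append = TRUE)
  invisible(entry)
}

read_world_artifacts <- function(config) {
  rd <- art(config, "rasters")
  env_files <- list.files(rd, pattern = "^env_.*\\.asc$", full.names = TRUE)
  if (!length(env_files))
    stop("missing artifact 'rasters/env_*.asc': run simulate first")
  nm <- sub("^env_", "", sub("\\.asc$", "", basename(env_files)))
  env_stack <- stats::setNames(lapply(env_files, read_ascii_grid), nm)
  # restore declared order (file listing is alphabetical)
  want <- intersect(c(config$mrm$climate_vars, config$mrm$elevation_var,
                      config$mrm$vegetation_vars), nm)
  env_stack <- env_stack[c(want, setdiff(nm, want))]
  class_grids <- list()
  for (cg in c("ecoregion", "clime")) {
    f <- file.path(rd, paste0(cg, ".asc"))
    if (file.exists(f)) class_grids[[cg]] <- read_ascii_grid(f)
  }
  list(env_stack = env_stack, class_grids = class_grids)
}

subset_assignment <- function(ass, keep) {
  sid <- ass$site_id[keep]
  sites <- ass$sites[ass$sites$site %in% unique(sid), , drop = FALSE]
  sites$n_records <- as.vector(table(factor(sid, levels = sites$site)))
  structure(list(site_id = sid, sites = sites, mcl = ass$mcl),
            class = "site_assignment")
}

#' Run one pipeline stage
#'
#' Stages (mirroring the processing flowchart): `simulate` (synthetic world,
#' rasters, occurrence CSV), `sites` (Markov clustering, boundary removal,
#' community matrix + filters), `extract` (per-site environmental table),
#' `dissim` (Horn-Morisita + geographic distance matrices, class contrasts),
#' `mrm` (nested model-comparison table), `gdm` (fit + predictor
#' significance), `map` (biological-space transform + PCA-RGB map). Each
#' stage writes its artifacts under `config$out_dir` plus a manifest line
#' with input/output hashes, the stage seed, and row counts; reruns on
#' unchanged inputs are bit-identical.
#'
#' @param stage one of `"simulate"`, `"sites"`, `"extract"`, `"dissim"`,
#'   `"mrm"`, `"gdm"`, `"map"`, or `"all"`.
#' @param config a [run_config()] object.
#' @return the stage's manifest entry (list), invisibly. `"all"` returns the
#'   list of entries.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c(stage_order, "all"))
  if (stage == "all") {
    return(invisible(lapply(stage_order, run_stage, config = config)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = stage_simulate(config),
         sites = stage_sites(config),
         extract = stage_extract(config),
         dissim = stage_dissim(config),
         mrm = stage_mrm(config),
         gdm = stage_gdm(config),
         map = stage_map(config))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) run_stage("all", config)

stage_simulate <- function(config) {
  wc <- config$world
  seed <- stage_seed(config, "simulate")
  world <- generate_world(wc$extent, wc$grid_shape, wc$n_env_vars,
                          wc$n_classes, seed = seed, n_climes = wc$n_climes)
  pool <- generate_species_pool(world, wc$n_species, seed = seed + 1L)
  eff <- effort_map(world, ratio = wc$effort_ratio)
  occ <- sample_occurrences(world, pool, eff, wc$n_records, seed = seed + 2L)
  rd <- art(config, "rasters")
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  outs <- character()
  for (nm in names(world$env_stack))
    outs <- c(outs, write_ascii_grid(world$env_stack[[nm]],
                                     file.path(rd, paste0("env_", nm, ".asc"))))
  outs <- c(outs, write_ascii_grid(world$class_grid,
                                   file.path(rd, "ecoregion.asc")))
  if (!is.null(world$clime_grid))
    outs <- c(outs, write_ascii_grid(world$clime_grid,
                                     file.path(rd, "clime.asc")))
  outs <- c(outs, write_ascii_grid(eff, file.path(rd, "effort.asc")),
            write_occurrences(occ, art(config, "occurrences.csv")))
  manifest_append(config, "simulate", character(), outs,
                  counts = list(n_records = nrow(occ),
                                n_species = length(unique(occ$species))))
}

stage_sites <- function(config) {
  occ_file <- require_artifact(config, "occurrences.csv", "simulate")
  eco_file <- require_artifact(config, file.path("rasters", "ecoregion.asc"),
                               "simulate")
  occ <- read_occurrences(occ_file)
  class_grid <- read_ascii_grid(eco_file)
  mp <- config$mcl
  params <- mcl_params(inflation = mp$inflation,
                       pre_inflation = mp$pre_inflation,
                       expansion = mp$expansion, edge_radius = mp$edge_radius,
                       kernel_bandwidth = mp$kernel_bandwidth,
                       prune_threshold = mp$prune_threshold,
                       max_iter = mp$max_iter,
                       convergence_tol = mp$convergence_tol)
  ass <- cluster_sites(occ$table, params, snap = mp$snap)
  bd <- remove_boundary_records(occ$table, class_grid,
                                rule = config$boundary_rule)
  keep <- rownames(occ$table) %in% rownames(bd$table)
  cm <- build_community_matrix(bd$table, subset_assignment(ass, keep))
  cmf <- filter_matrix(cm, config$filters$min_sites_per_species,
                       config$filters$min_obs_per_site)
  outs <- c(write_community_matrix(cmf, art(config, "community.csv"),
                                   art(config, "sites.csv")),
            art(config, "sites.csv"))
  rep <- attr(cmf, "filter_report")
  manifest_append(
    config, "sites", c(occ_file, eco_file), outs,
    counts = list(n_read = unname(occ$report["n_read"]),
                  n_dropped_parse = unname(occ$report["n_read"] -
                                             occ$report["n_kept"]),
                  n_dropped_boundary = bd$n_removed,
                  n_dropped_filter = sum(cm) - sum(cmf),
                  n_retained = sum(cmf),
                  n_sites = nrow(cmf), n_species = ncol(cmf)))
}

stage_extract <- function(config) {
  site_file <- require_artifact(config, "sites.csv", "sites")
  sites <- utils::read.csv(site_file)
  wa <- read_world_artifacts(config)
  env <- build_env_table(sites, wa$env_stack, wa$class_grids)
  out <- art(config, "env.csv")
  utils::write.csv(env, out, row.names = FALSE)
  manifest_append(config, "extract", site_file, out,
                  counts = list(n_sites = nrow(env),
                                n_excluded = length(attr(env, "excluded"))))
}

stage_dissim <- function(config) {
  cm_file <- require_artifact(config, "community.csv", "sites")
  env_file <- require_artifact(config, "env.csv", "extract")
  cm <- read_community_matrix(cm_file, art(config, "sites.csv"))
  env <- utils::read.csv(env_file)
  # align community matrix to the sites retained by extraction
  cm2 <- cm[rownames(cm) %in% as.character(env$site), , drop = FALSE]
  D <- pairwise_dissimilarity(cm2, variant = config$dissimilarity$variant)
  cent <- env[match(rownames(cm2), as.character(env$site)), ]
  G <- geographic_distance(cent[, c("lat", "lon")])
  dimnames(G) <- dimnames(D)
  seed <- stage_seed(config, "dissim")
  contrasts <- do.call(rbind, lapply(
    intersect(c("ecoregion", "clime"), names(env)), function(cl) {
      cc <- class_contrast(D, cent[[cl]], n_perm = config$mrm$n_perm,
                           seed = seed)
      data.frame(classification = cl, r = cc$r, p = cc$p, n_perm = cc$n_perm)
    }))
  outs <- c(write_dist_matrix(D, art(config, "dissimilarity.csv")),
            write_dist_matrix(G, art(config, "geographic.csv")))
  if (!is.null(contrasts)) {
    utils::write.csv(contrasts, art(config, "contrasts.csv"),
                     row.names = FALSE)
    outs <- c(outs, art(config, "contrasts.csv"))
  }
  manifest_append(config, "dissim", c(cm_file, env_file), outs,
                  counts = list(n_sites = nrow(cm2)))
}

stage_mrm <- function(config) {
  d_file <- require_artifact(config, "dissimilarity.csv", "dissim")
  g_file <- require_artifact(config, "geographic.csv", "dissim")
  env_file <- require_artifact(config, "env.csv", "extract")
  D <- read_dist_matrix(d_file)
  G <- read_dist_matrix(g_file)
  env <- utils::read.csv(env_file)
  env <- env[match(rownames(D), as.character(env$site)), ]
  cl <- intersect(config$mrm$climate_vars, names(env))
  vg <- intersect(config$mrm$vegetation_vars, names(env))
  tab <- model_comparison(D, G, env_distances(env, cl), env_distances(env, vg),
                          n_perm = config$mrm$n_perm,
                          seed = stage_seed(config, "mrm"))
  out <- art(config, "mrm_table.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  manifest_append(config, "mrm", c(d_file, g_file, env_file), out,
                  counts = list(n_models = nrow(tab)))
}

gdm_predictor_set <- function(config, env) {
  intersect(c("lat", "lon", config$mrm$elevation_var,
              config$mrm$climate_vars, config$mrm$vegetation_vars),
            names(env))
}

stage_gdm <- function(config) {
  d_file <- require_artifact(config, "dissimilarity.csv", "dissim")
  env_file <- require_artifact(config, "env.csv", "extract")
  cm_file <- require_artifact(config, "community.csv", "sites")
  D <- read_dist_matrix(d_file)
  env <- utils::read.csv(env_file)
  env <- env[match(rownames(D), as.character(env$site)), ]
  cm <- read_community_matrix(cm_file)
  cm <- cm[match(rownames(D), rownames(cm)), , drop = FALSE]
  richness <- rowSums(unclass_cm(cm) > 0)
  pairs <- build_site_pairs(D, env, richness,
                            predictors = gdm_predictor_set(config, env))
  model <- fit_gdm(pairs, n_splines = config$gdm$n_splines)
  sig <- predictor_significance(pairs, n_splines = config$gdm$n_splines,
                                n_perm = config$gdm$n_perm,
                                seed = stage_seed(config, "gdm"),
                                alpha = config$gdm$alpha, model = model)
  outs <- c(write_gdm_model(model, art(config, "gdm_model.json")))
  utils::write.csv(sig, art(config, "gdm_significance.csv"),
                   row.names = FALSE)
  outs <- c(outs, art(config, "gdm_significance.csv"))
  manifest_append(config, "gdm", c(d_file, env_file, cm_file), outs,
                  counts = list(
                    n_pairs = nrow(pairs),
                    pct_deviance_explained = model$pct_deviance_explained,
                    n_significant = sum(sig$keep)))
}

stage_map <- function(config) {
  model_file <- require_artifact(config, "gdm_model.json", "gdm")
  sig_file <- require_artifact(config, "gdm_significance.csv", "gdm")
  model <- read_gdm_model(model_file)
  sig <- utils::read.csv(sig_file)
  wa <- read_world_artifacts(config)
  keep <- sig$predictor[sig$keep & sig$importance > 0]
  if (!length(keep)) keep <- sig$predictor[sig$importance > 0]
  tr <- transform_env(model, wa$env_stack, predictors = keep)
  map <- beta_map(tr)
  outs <- write_rgb_map(map, art(config, "beta_map"))
  manifest_append(config, "map", c(model_file, sig_file), outs,
                  counts = list(n_layers = length(tr)))
}
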
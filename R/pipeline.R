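#' Pipeline configuration
#'
#' Assembles the resolved parameter set for [run_pipeline()]: either
#' synthetic specs (a [stand_spec()] and a [geno_sim_spec()]) or input file
#' paths, plus every stage parameter. The resolved configuration is written
#' as YAML next to the outputs of every run, and `save_config()` /
#' `load_config()` round-trip it.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param stand a [stand_spec()] (used when `cloud_file` is `NULL`).
#' @param geno a [geno_sim_spec()] (used when `genotype_file` is `NULL`);
#'   its `n` is reconciled to the number of segmented trees.
#' @param cloud_file optional path to a point cloud (XYZ/PLY).
#' @param genotype_file optional path to a GenAlEx-like CSV.
#' @param cell_size DEM/CHM cell size (m).
#' @param k_graph neighbours in the segmentation graph.
#' @param K_range admixture K scan range (contiguous).
#' @param n_runs admixture runs per K.
#' @param iters,burn_in Gibbs sweeps and burn-in per run.
#' @param ccr_threshold PCA cumulative contribution threshold (%).
#' @param inclusion_rate fraction of trees selected per genetic group.
#' @return a `pipeline_config` (plain named list).
#' @export
pipeline_config <- function(out_dir = "plustree_out", seed = 1L,
                            stand = stand_spec(n_trees = 20, seed = seed),
                            geno = geno_sim_spec(K = 3, n = 60, seed = seed),
                            cloud_file = NULL, genotype_file = NULL,
                            cell_size = 0.1, k_graph = 5,
                            K_range = 1:5, n_runs = 3L,
                            iters = 2000L, burn_in = 500L,
                            ccr_threshold = 85, inclusion_rate = 0.10) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stand = unclass(stand), geno = unclass(geno),
                 cloud_file = cloud_file, genotype_file = genotype_file,
                 cell_size = cell_size, k_graph = k_graph,
                 K_range = as.integer(K_range), n_runs = as.integer(n_runs),
                 iters = as.integer(iters), burn_in = as.integer(burn_in),
                 ccr_threshold = ccr_threshold, inclusion_rate = inclusion_rate),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(.simplify_config(unclass(config)), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$stand$crown_radii <- matrix(unlist(cfg$stand$crown_radii), ncol = 2,
                                  byrow = TRUE)
  structure(cfg, class = "pipeline_config")
}

.simplify_config <- function(x) {
  rapply(x, function(v) if (is.matrix(v)) apply(v, 1, as.list, simplify = FALSE) else v,
         how = "replace")
}

#' Run the full screening pipeline
#'
#' Executes the whole workflow in order: obtain data (simulate or load),
#' filter ground and build the DEM, normalize heights, detect trunks,
#' segment trees, extract structural traits, add component biomass, compute
#' SSR diversity statistics, Nei distances and the NJ tree, scan the
#' admixture model over K, pick K by Evanno delta-K, assign genetic groups,
#' and rank/select trees per group by the contribution-weighted PCA score.
#' All tables are written as CSV (plus Newick for the tree and YAML for the
#' resolved config) under `config$out_dir`. Deterministic given
#' `config$seed`. Any stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list: `traits` (13-characteristic table),
#'   `diversity`, `distance`, `newick`, `delta_k`, `groups`, `selection`,
#'   `summary` (selected ids and counts per group), `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name, writer = utils::write.csv, ...) {
    p <- file.path(config$out_dir, name)
    writer(obj, p, ...)
    files[[length(files) + 1L]] <<- p
    p
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[plustree] %-12s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  # --- data ------------------------------------------------------------
  cloud <- stage("data", {
    if (!is.null(config$cloud_file)) read_cloud(config$cloud_file)
    else generate_stand(do.call(stand_spec, config$stand))$cloud
  })

  # --- segmentation ----------------------------------------------------
  seg <- stage("segment", {
    gmask <- filter_ground(cloud)
    dem <- build_dem(cloud[gmask, ], cell_size = config$cell_size)
    normed <- normalize_heights(cloud, dem)
    veg <- normed[!gmask & normed$z > 0.1, , drop = FALSE]
    seeds <- detect_trunks(veg)
    if (nrow(seeds) == 0L) stop("no trunk seeds detected")
    segment_trees(veg, seeds, k = config$k_graph)
  })

  # --- traits + biomass ------------------------------------------------
  traits <- stage("traits", {
    tt <- do.call(rbind, lapply(seg, extract_traits))
    tt <- cbind(tt, biomass(tt$DBH, tt$H))
    rownames(tt) <- paste0("T", seq_len(nrow(tt)))
    # canonical characteristic order
    tt[, c("H", "DBH", "CW", "CA", "CV", "TV", "HLC",
           "LB", "BB", "TB", "AGB", "RB", "WPB")]
  })
  emit(data.frame(id = rownames(traits), traits), "traits.csv", row.names = FALSE)

  # --- genotypes -------------------------------------------------------
  geno <- stage("genotypes", {
    if (!is.null(config$genotype_file)) read_genalex_csv(config$genotype_file)
    else {
      ga <- config$geno
      ga$n <- nrow(traits)          # one genotype per segmented tree
      g <- generate_genotypes(do.call(geno_sim_spec, ga))$genotypes
      g$ids <- rownames(traits)
      dimnames(g$a1)[[1]] <- dimnames(g$a2)[[1]] <- g$ids
      g
    }
  })
  if (length(geno$ids) != nrow(traits))
    stop("pipeline stage 'genotypes' failed: ", length(geno$ids),
         " genotypes vs ", nrow(traits), " segmented trees")

  # --- population genetics --------------------------------------------
  pg <- stage("popgen", {
    div <- diversity_stats(geno)
    D <- nei_distance(geno)
    nj <- nj_tree(D)
    scan <- admixture_scan(geno, K_range = config$K_range,
                           n_runs = config$n_runs, iters = config$iters,
                           burn_in = config$burn_in, seed = config$seed)
    dk <- delta_k(scan$loglik)
    k_opt <- if (is.na(dk$optimal_k)) min(config$K_range[config$K_range > 1]) else dk$optimal_k
    fit <- scan$fits[[as.character(k_opt)]][[1]]
    groups <- assign_groups(fit, "admixture")
    list(div = div, D = D, nj = nj, scan = scan, dk = dk, k = k_opt,
         fit = fit, groups = groups)
  })
  emit(pg$div$per_locus, "diversity.csv", row.names = FALSE)
  emit(as.data.frame(pg$D), "nei_distance.csv")
  emit(pg$nj$newick, "nj_tree.nwk", writer = function(x, p) writeLines(x, p))
  emit(data.frame(id = rownames(pg$fit$Q), pg$fit$Q), "q_matrix.csv", row.names = FALSE)
  emit(data.frame(K = as.integer(names(pg$dk$delta_k)), delta_k = pg$dk$delta_k),
       "delta_k.csv", row.names = FALSE)

  # --- evaluation ------------------------------------------------------
  ev <- stage("evaluate", {
    evaluate_groups(traits, pg$groups[rownames(traits)],
                    ids = rownames(traits),
                    ccr_threshold = config$ccr_threshold,
                    inclusion_rate = config$inclusion_rate)
  })
  emit(ev$selection, "selection.csv", row.names = FALSE)
  for (grp in names(ev$pca)) {
    fit <- ev$pca[[grp]]
    rep_tab <- data.frame(trait = rownames(fit$loadings),
                          round(fit$loadings[, seq_len(ev$m[[grp]]), drop = FALSE], 3))
    emit(rep_tab, paste0("pca_group", grp, ".csv"), row.names = FALSE)
  }
  emit(structure(config, class = NULL), "config.yaml",
       writer = function(x, p) yaml::write_yaml(.simplify_config(x), p))

  sel <- ev$selection[ev$selection$selected, ]
  summary <- list(
    n_trees = nrow(traits),
    optimal_k = pg$k,
    group_sizes = as.list(table(pg$groups)),
    selected = split(sel$id, sel$group),
    n_selected = nrow(sel))
  res <- list(traits = traits, diversity = pg$div, distance = pg$D,
              newick = pg$nj$newick, delta_k = pg$dk, groups = pg$groups,
              selection = ev$selection, summary = summary,
              files = unlist(files))
  invisible(res)
}
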
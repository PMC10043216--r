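#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON. See [run_pipeline()] for the recognised
#' fields.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_tsv_artifact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_artifact <- function(m, path, id_column = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv_artifact(df, path)
}

#' Run the full analysis pipeline from a configuration file
#'
#' Orchestrates simulation (or loading) of a count table, tree, and
#' metadata, then the diversity, assembly, and network stages, writing
#' per-stage TSV/JSON artifacts plus a `manifest.json` that records the
#' config file's MD5 hash, the root seed, every derived stage seed, and the
#' artifact list — the reproducibility contract: rerunning with the same
#' config and seed reproduces every artifact byte for byte.
#'
#' Config fields (YAML or JSON): `seed` (root seed), `reps` (null-model
#' replicates, >= 1), `out_dir`; `input: {counts, tree, metadata}` (TSV /
#' Newick paths) or `simulate: {scenario, n_taxa, n_samples, n_groups,
#' depth, trait_sigma, selection_strength}`; `diversity: {rarefy_depth,
#' n_perm}`; `assembly: {n_top, nti_threshold, rc_threshold}`; `network:
#' {min_prevalence, r_threshold, p_threshold, n_perm, n_null_iter}`.
#'
#' @param config_path Path to the configuration file.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @param stages Subset of `c("diversity", "assembly", "network")` to run
#'   (default all).
#' @return Invisibly, a result bundle: the inputs, per-stage results, and
#'   the manifest.
#' @export
run_pipeline <- function(config_path, out_dir = NULL,
                         stages = c("diversity", "assembly", "network")) {
  cfg <- read_config(config_path)
  stages <- match.arg(stages, several.ok = TRUE)

  # -- validate configuration before any computation ------------------------
  seed <- cfg$seed %||% 1L
  reps <- cfg$reps %||% 999L
  if (!is.numeric(reps) || reps < 1) {
    stop("configuration error: 'reps' must be >= 1")
  }
  out_dir <- out_dir %||% cfg$out_dir %||% stop("configuration error: no out_dir")
  inp <- cfg$input
  if (!is.null(inp$counts)) {
    for (f in c(inp$counts, inp$tree, inp$metadata)) {
      if (!is.null(f) && !file.exists(f)) {
        stop("configuration error: input file not found: ", f)
      }
    }
  } else if (is.null(cfg$simulate)) {
    stop("configuration error: provide either 'input' paths or a 'simulate' block")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seeds <- stats::setNames(split_seed(seed, 8),
                           c("simulate", "rarefy", "permanova", "beta_nti",
                             "rc_bray", "nst", "sparcc", "cohesion"))
  artifacts <- character(0)
  results <- list()

  # -- inputs ----------------------------------------------------------------
  if (!is.null(inp$counts)) {
    counts <- read_count_table(inp$counts)
    tree <- if (!is.null(inp$tree)) read_tree(inp$tree) else NULL
    metadata <- if (!is.null(inp$metadata)) {
      read_metadata(inp$metadata, group_column = cfg$group_column %||% "group")
    } else NULL
  } else {
    sim_cfg <- cfg$simulate
    study <- simulate_study(
      seed = seeds[["simulate"]],
      n_taxa = sim_cfg$n_taxa %||% 500,
      n_samples = sim_cfg$n_samples %||% 54,
      n_groups = sim_cfg$n_groups %||% 4,
      depth = sim_cfg$depth %||% 10000,
      scenario = sim_cfg$scenario %||% "heterogeneous_selection",
      trait_sigma = sim_cfg$trait_sigma %||% 1,
      selection_strength = sim_cfg$selection_strength %||% 5)
    counts <- study$counts
    tree <- study$tree
    metadata <- study$metadata
    artifacts <- c(artifacts,
      write_count_table(counts, file.path(out_dir, "counts.tsv")),
      write_tsv_artifact(metadata, file.path(out_dir, "metadata.tsv")))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    artifacts <- c(artifacts, file.path(out_dir, "tree.nwk"))
  }
  groups <- if (!is.null(metadata)) {
    metadata$group[match(colnames(counts), metadata$sample_id)]
  } else NULL

  div_cfg <- cfg$diversity %||% list()
  if (!is.null(div_cfg$rarefy_depth)) {
    counts <- rarefy(counts, div_cfg$rarefy_depth, seed = seeds[["rarefy"]])
    if (!is.null(groups)) {
      groups <- metadata$group[match(colnames(counts), metadata$sample_id)]
    }
  }

  # -- diversity -------------------------------------------------------------
  if ("diversity" %in% stages) {
    alpha <- alpha_diversity(counts)
    bc <- bray_curtis(counts)
    jc <- jaccard(counts)
    artifacts <- c(artifacts,
      write_tsv_artifact(alpha, file.path(out_dir, "alpha_diversity.tsv")),
      write_matrix_artifact(as.matrix(bc),
                            file.path(out_dir, "bray_curtis.tsv"), "sample_id"),
      write_matrix_artifact(as.matrix(jc),
                            file.path(out_dir, "jaccard.tsv"), "sample_id"))
    results$diversity <- list(alpha = alpha, bray_curtis = bc, jaccard = jc)
    if (!is.null(groups) && length(unique(groups)) >= 2) {
      pmv <- permanova(bc, groups, n_perm = div_cfg$n_perm %||% 999,
                       seed = seeds[["permanova"]])
      venn <- group_taxon_sets(counts, groups)
      f <- file.path(out_dir, "permanova.json")
      jsonlite::write_json(pmv, f, auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, f,
        write_tsv_artifact(data.frame(region = names(venn),
                                      n_taxa = as.integer(venn)),
                           file.path(out_dir, "venn_regions.tsv")))
      results$diversity$permanova <- pmv
      results$diversity$venn <- venn
    }
  }

  # -- assembly --------------------------------------------------------------
  if ("assembly" %in% stages) {
    if (is.null(tree)) stop("configuration error: assembly stage needs a tree")
    asm_cfg <- cfg$assembly %||% list()
    tab <- filter_top_taxa(counts, asm_cfg$n_top %||% min(100, nrow(counts)))
    bnti <- beta_nti(tab, tree, n_reps = reps, seed = seeds[["beta_nti"]])
    rc <- rc_bray(tab, n_reps = reps, seed = seeds[["rc_bray"]])
    pairs <- pair_assembly(bnti, rc,
                           nti_threshold = asm_cfg$nti_threshold %||% 2,
                           rc_threshold = asm_cfg$rc_threshold %||% 0.95)
    artifacts <- c(artifacts,
      write_tsv_artifact(pairs, file.path(out_dir, "pair_assembly.tsv")))
    results$assembly <- list(pairs = pairs)
    if (!is.null(groups)) {
      if (any(!is.na(pairs$process))) {
        summ <- assembly_summary(pairs, metadata)
        artifacts <- c(artifacts,
          write_tsv_artifact(summ, file.path(out_dir, "assembly_summary.tsv")))
        results$assembly$summary <- summ
      } else {
        warning("no classified sample pairs; assembly summary skipped")
      }
      nst_tab <- nst(tab, groups, n_reps = reps, seed = seeds[["nst"]])
      artifacts <- c(artifacts,
        write_tsv_artifact(nst_tab, file.path(out_dir, "nst.tsv")))
      results$assembly$nst <- nst_tab
    }
  }

  # -- network ---------------------------------------------------------------
  if ("network" %in% stages) {
    net_cfg <- cfg$network %||% list()
    nt <- prevalence_filter(counts, net_cfg$min_prevalence %||% 0.2)
    sp <- sparcc_pvalues(nt, n_perm = net_cfg$n_perm %||% 100,
                         seed = seeds[["sparcc"]])
    g <- build_network(sp$rho, sp$p,
                       r_threshold = net_cfg$r_threshold %||% 0.3,
                       p_threshold = net_cfg$p_threshold %||% 0.05)
    mods <- detect_modules(g)
    topo <- topology_report(g, mods)
    coh <- cohesion(nt, n_null_iter = net_cfg$n_null_iter %||% 200,
                    seed = seeds[["cohesion"]])
    f <- file.path(out_dir, "topology.json")
    jsonlite::write_json(unclass(topo), f, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, f,
      write_network(g, file.path(out_dir, "network_edges.tsv")),
      write_tsv_artifact(coh$cohesion, file.path(out_dir, "cohesion.tsv")))
    results$network <- list(graph = g, correlations = sp$rho, pvalues = sp$p,
                            modules = mods, topology = topo, cohesion = coh)
    if (igraph::vcount(g) > 0) {
      roles <- zc_scores(g, mods)
      rob <- robustness_curve(g)
      artifacts <- c(artifacts,
        write_tsv_artifact(roles, file.path(out_dir, "node_roles.tsv")),
        write_tsv_artifact(rob$curve, file.path(out_dir, "robustness.tsv")))
      results$network$roles <- roles
      results$network$robustness <- rob
    }
  }

  manifest <- list(config = config_path,
                   config_md5 = unname(tools::md5sum(config_path)),
                   seed = seed, stage_seeds = as.list(seeds), reps = reps,
                   stages = stages, artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
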
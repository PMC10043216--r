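#' Scenario configuration for synthetic community simulation
#'
#' Bundles the parameters of [simulate_community()] into a validated recipe.
#' Each scenario corresponds to one of the five community-assembly processes
#' routinely distinguished in null-model analyses of microbiome data:
#' heterogeneous selection (HeS), homogeneous selection (HoS), dispersal
#' limitation (DL), homogenizing dispersal (HD), and undominated (UD).
#'
#' @param scenario One of `"homogeneous_selection"`,
#'   `"heterogeneous_selection"`, `"dispersal_limitation"`,
#'   `"homogenizing_dispersal"`, `"undominated"`.
#' @param n_taxa Number of taxa (>= 2).
#' @param n_samples Number of samples (>= 2).
#' @param n_groups Number of sample groups (e.g. vegetation types).
#' @param depth Sequencing depth: reads per sample (>= 1).
#' @param trait_sigma Brownian-motion rate of the niche trait
#'   (trait units^2 per unit branch length).
#' @param selection_strength Strength of the Gaussian environmental filter
#'   (dimensionless, >= 0); only used by the selection scenarios.
#' @param migration_rate Fraction of each site's pool drawn from the shared
#'   metacommunity, in `[0, 1]`. Defaults: 0.01 for `dispersal_limitation`,
#'   0.95 for `homogenizing_dispersal`, 1 for `undominated` (pure shared
#'   pool), 0 for the selection scenarios (within the selected guild all
#'   turnover comes from drift, which drives the turnover among close
#'   relatives that the phylogenetic null model detects).
#' @param drift_theta Concentration of the Dirichlet demographic noise
#'   around the (selection-weighted) pool; smaller = stronger abundance
#'   drift, `Inf` disables drift. Defaults: 50 for the selection scenarios,
#'   5 for the neutral ones.
#' @param pool_alpha Dirichlet concentration of the shared metacommunity
#'   pool (smaller = more uneven taxon abundances).
#' @param env_optimum Environmental optimum of homogeneous selection in
#'   standardized trait units, or `NA` (default) to place the optimum
#'   automatically on an occupied niche admitting about `guild_frac` of the
#'   pool (heterogeneous selection always picks its two contrasting optima
#'   automatically, one per trait tail).
#' @param guild_frac Target fraction of the taxon pool inside the
#'   1%-fitness niche window when optima are placed automatically.
#' @param retain_p Per-taxon colonisation (retention) probability of the
#'   drift lottery; presence turnover between sites comes from this
#'   thinning.
#' @param seed Integer seed driving every random draw in the scenario.
#' @return An object of class `"scenario_config"` (a named list).
#' @export
#' @examples
#' cfg <- scenario_config("undominated", n_taxa = 20, n_samples = 6, seed = 1)
scenario_config <- function(scenario = c("homogeneous_selection",
                                         "heterogeneous_selection",
                                         "dispersal_limitation",
                                         "homogenizing_dispersal",
                                         "undominated"),
                            n_taxa = 50, n_samples = 20, n_groups = 2,
                            depth = 10000, trait_sigma = 1,
                            selection_strength = 10,
                            migration_rate = NULL,
                            drift_theta = NULL,
                            pool_alpha = 2,
                            env_optimum = NA_real_,
                            guild_frac = 0.18,
                            retain_p = 0.5,
                            seed = 1) {
  scenario <- match.arg(scenario)
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (depth < 1) stop("depth must be >= 1")
  if (trait_sigma < 0) stop("trait_sigma must be >= 0")
  if (selection_strength < 0) stop("selection_strength must be >= 0")
  if (is.null(migration_rate)) {
    migration_rate <- switch(scenario,
      dispersal_limitation = 0.01,
      homogenizing_dispersal = 0.95,
      undominated = 1,
      0)
  }
  if (is.null(drift_theta)) {
    drift_theta <- switch(scenario,
      homogeneous_selection = ,
      heterogeneous_selection = 50,
      5)
  }
  if (retain_p <= 0 || retain_p > 1) stop("retain_p must be in (0, 1]")
  if (migration_rate < 0 || migration_rate > 1) {
    stop("migration_rate must be in [0, 1]")
  }
  if (scenario == "dispersal_limitation" && migration_rate > 0.05) {
    stop("dispersal_limitation requires migration_rate <= 0.05")
  }
  if (scenario == "homogenizing_dispersal" && migration_rate < 0.9) {
    stop("homogenizing_dispersal requires migration_rate >= 0.9")
  }
  structure(list(scenario = scenario, n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples),
                 n_groups = as.integer(n_groups),
                 depth = as.integer(depth), trait_sigma = trait_sigma,
                 selection_strength = selection_strength,
                 migration_rate = migration_rate,
                 drift_theta = drift_theta,
                 pool_alpha = pool_alpha,
                 env_optimum = env_optimum,
                 guild_frac = guild_frac,
                 retain_p = retain_p,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a rooted ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with unit speciation rate; tips are relabelled
#' `t1..tn`. Ultrametric by construction, so root-to-tip depths are equal
#' and cophenetic distances are twice the divergence times.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; the same seed reproduces the same Newick string.
#' @return An [ape::phylo] object.
#' @export
#' @examples
#' tree <- simulate_phylogeny(10, seed = 1)
simulate_phylogeny <- function(n_taxa, seed = 1) {
  if (!is.numeric(n_taxa) || n_taxa < 2) stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(as.integer(n_taxa), birth = 1, death = 0))
  tree$tip.label <- paste0("t", seq_len(as.integer(n_taxa)))
  tree
}

#' Evolve a continuous niche trait along a phylogeny
#'
#' Brownian motion from a root value of 0, so a tip's marginal variance is
#' `trait_sigma` times its root-to-tip path length and closely related taxa
#' carry similar trait values (the phylogenetically conserved niche that
#' selection scenarios filter on).
#'
#' `conservatism` is a Pagel-delta-style exponent on node depths: values
#' below 1 concentrate trait divergence on the deep branches, giving the
#' clade-level niche conservatism (habitat preferences shared across whole
#' clades) that phylogenetic null models assume; 1 is plain Brownian
#' motion. Node depths are rescaled as `T * (t/T)^conservatism`, so on an
#' ultrametric tree every tip keeps its root-to-tip length and the marginal
#' tip variance above is unchanged — only the allocation of divergence
#' along the path shifts.
#'
#' @param tree An [ape::phylo] object.
#' @param trait_sigma Brownian rate (variance per unit branch length), >= 0.
#' @param seed Integer seed.
#' @param conservatism Depth-transform exponent in `(0, Inf)`; default 0.2
#'   (deeply conserved niches). Use 1 for plain Brownian motion.
#' @return Named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, trait_sigma = 1, seed = 1,
                         conservatism = 0.2) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!is.numeric(trait_sigma) || trait_sigma < 0) {
    stop("trait_sigma must be >= 0")
  }
  if (!is.numeric(conservatism) || conservatism <= 0) {
    stop("conservatism must be > 0")
  }
  tr <- tree
  if (conservatism != 1) {
    depth <- ape::node.depth.edgelength(tree)
    H <- max(depth)
    nd <- H * (depth / H)^conservatism
    tr$edge.length <- nd[tree$edge[, 2]] - nd[tree$edge[, 1]]
  }
  with_seed(seed, ape::rTraitCont(tr, model = "BM",
                                  sigma = sqrt(trait_sigma),
                                  root.value = 0))
}

# Deterministic placement of environmental optima on the standardized
# trait axis. Candidate optima are the taxa's own trait values; a
# candidate's guild is every taxon inside its 1%-fitness niche window.
# Among candidates whose guild size is moderate (4 to 2x the target),
# the phylogenetically tightest guild wins -- niches are clade-structured,
# so the filter should land on a coherent clade rather than in a gap
# between clade-level trait blocks. Returns the optima plus a tightness
# ratio (guild mean nearest-taxon distance over the random-subset
# expectation; small = coherent guild).
select_optima <- function(tree, traits, config) {
  taxa <- tree$tip.label
  traits <- traits[taxa]
  zt <- (traits - mean(traits)) / stats::sd(traits)
  guild_target <- max(4L, round(config$guild_frac * config$n_taxa))
  phyd <- stats::cophenetic(tree)[taxa, taxa]
  diag(phyd) <- NA
  mean_nn <- function(g) {
    mean(apply(phyd[g, g, drop = FALSE], 1, min, na.rm = TRUE))
  }
  guild_of <- function(opt) {
    which(exp(-config$selection_strength * (zt - opt)^2) >= 0.01)
  }
  pick <- function(cands, top = 1) {
    guilds <- lapply(cands, guild_of)
    sizes <- lengths(guilds)
    ok <- sizes >= 4 & sizes <= 2 * guild_target
    if (!any(ok)) return(cands[which.min(abs(sizes - guild_target))])
    tight <- vapply(guilds[ok], mean_nn, numeric(1))
    cands[ok][order(tight)][seq_len(min(top, sum(ok)))]
  }
  optima <- if (config$scenario == "homogeneous_selection") {
    if (is.na(config$env_optimum)) {
      pick(zt[zt > stats::median(zt)])
    } else config$env_optimum
  } else {
    # contrasting optima: among the tightest guilds of each trait tail,
    # take the pair of guilds that are farthest apart on the tree
    lo <- pick(zt[zt < stats::quantile(zt, 0.35)], top = 3)
    hi <- pick(zt[zt > stats::quantile(zt, 0.65)], top = 3)
    cross <- expand.grid(lo = lo, hi = hi)
    sep <- apply(cross, 1, function(p) {
      mean(phyd[guild_of(p[["lo"]]), guild_of(p[["hi"]])], na.rm = TRUE)
    })
    unlist(cross[which.max(sep), ], use.names = FALSE)
  }
  guilds <- lapply(optima, guild_of)
  # reference: mean nearest-taxon distance of size-matched random subsets
  # (fixed internal seed; purely a diagnostic scale)
  ratio <- max(vapply(guilds, function(g) {
    if (length(g) < 2) return(Inf)
    ref <- with_seed(7, mean(replicate(30, {
      mean_nn(sample(length(taxa), length(g)))
    })))
    mean_nn(g) / ref
  }, numeric(1)))
  list(optima = unname(optima), guilds = guilds, tightness = ratio)
}

#' Simulate group-structured communities under a known assembly process
#'
#' Every scenario starts from a shared metacommunity pool and a per-site
#' pool `q_s = (1 - m) * drifted pool + m * shared pool`, where the drifted
#' pool is Dirichlet-resampled around the shared pool with concentration
#' `drift_theta` and `m` is `migration_rate` (so `m = 1`, the undominated
#' default, is pure shared-pool sampling). Selection scenarios additionally
#' weight each taxon by the Gaussian fitness
#' `exp(-selection_strength * (trait_i - e_s)^2)` toward the sample's
#' environmental optimum `e_s`: one shared optimum in a trait tail (mean +
#' 2 sd) under homogeneous selection, two contrasting optima (mean +/- 2 sd)
#' alternated across groups under heterogeneous selection. With
#' `selection_strength = 0` and `migration_rate = 1` the selection scenarios
#' reduce exactly to the undominated scenario. Counts are multinomial draws
#' of `depth` reads per sample.
#'
#' @param config A [scenario_config()].
#' @param tree Phylogeny whose tips are the simulated taxa.
#' @param traits Named trait vector covering all tips (from
#'   [evolve_trait()]).
#' @return A list with `counts` (taxa x samples integer matrix, columns
#'   summing to `depth`) and `metadata` (data frame with `sample_id`,
#'   `group`, `env`).
#' @export
simulate_community <- function(config, tree, traits) {
  stopifnot(inherits(config, "scenario_config"), inherits(tree, "phylo"))
  taxa <- tree$tip.label
  if (length(taxa) != config$n_taxa) {
    stop("tree has ", length(taxa), " tips but config expects ", config$n_taxa)
  }
  if (!all(taxa %in% names(traits))) {
    stop("traits do not cover all tree tips")
  }
  traits <- traits[taxa]
  n <- config$n_samples
  groups <- sort(paste0("G", rep_len(seq_len(config$n_groups), n)))
  sample_ids <- sprintf("s%02d", seq_len(n))

  zt <- (traits - mean(traits)) / stats::sd(traits)
  sel <- config$scenario %in% c("homogeneous_selection",
                                "heterogeneous_selection")
  env0 <- rep(NA_real_, n)
  if (sel) {
    opt <- select_optima(tree, traits, config)
    if (config$scenario == "homogeneous_selection") {
      env0[] <- opt$optima[1]
    } else {
      gidx <- as.integer(factor(groups))
      env0 <- opt$optima[(gidx - 1L) %% 2L + 1L]
    }
  }

  out <- with_seed(config$seed, {
    # Metacommunity pool: Dirichlet(pool_alpha); lower alpha gives the
    # uneven, long-tailed rank-abundance shape of amplicon surveys.
    g <- stats::rgamma(config$n_taxa, shape = config$pool_alpha)
    pool <- g / sum(g)
    env <- env0

    probs <- matrix(0, nrow = config$n_taxa, ncol = n)
    for (s in seq_len(n)) {
      # selection first: the environment defines the niche-feasible pool,
      # then ecological drift reshuffles abundance within it
      base <- if (config$scenario %in% c("homogeneous_selection",
                                         "heterogeneous_selection")) {
        fit <- exp(-config$selection_strength * (zt - env[s])^2)
        # hard niche boundary: taxa below 1% of peak fitness cannot
        # establish (prevents freak colonisation far outside the niche)
        fit[fit < 0.01] <- 0
        pool * fit
      } else pool
      if (sum(base) <= 0) stop("degenerate sampling weights in sample ", s)
      base <- base / sum(base)
      w <- if (config$migration_rate >= 1 || !is.finite(config$drift_theta)) {
        base
      } else {
        # drift = colonisation lottery (independent Bernoulli retention)
        # plus demographic noise (Dirichlet resampling of the retained
        # taxa); the lottery drives presence turnover, the resampling
        # abundance turnover
        keep <- stats::rbinom(config$n_taxa, 1, config$retain_p)
        d <- keep * stats::rgamma(config$n_taxa,
                                  shape = config$drift_theta * base)
        if (sum(d) == 0) d <- base
        (1 - config$migration_rate) * d / sum(d) +
          config$migration_rate * base
      }
      if (sum(w) <= 0) stop("degenerate sampling weights in sample ", s)
      probs[, s] <- w / sum(w)
    }
    counts <- vapply(seq_len(n),
                     function(s) stats::rmultinom(1, config$depth, probs[, s])[, 1],
                     integer(config$n_taxa))
    list(counts = counts, env = env)
  })

  counts <- out$counts
  dimnames(counts) <- list(taxa, sample_ids)
  storage.mode(counts) <- "integer"
  metadata <- data.frame(sample_id = sample_ids, group = groups,
                         env = out$env, stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

#' Simulate compositional counts with a known basis correlation structure
#'
#' Latent (basis) abundances are log-normal: per sample, log-abundances are
#' multivariate normal with unit log-scale variances, the supplied
#' correlation matrix, and taxon means drawn once from N(0, 1). Each sample
#' is closed to fractions and multinomially sampled to `depth`, mimicking
#' the compositional distortion that SparCC corrects for. The true basis
#' correlation matrix is attached as attribute `"basis_corr"` for recovery
#' scoring.
#'
#' @param n_taxa Number of taxa.
#' @param n_samples Number of samples.
#' @param basis_corr Symmetric positive-definite correlation matrix with
#'   unit diagonal (`n_taxa` x `n_taxa`).
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return Integer count matrix (taxa x samples) with columns summing to
#'   `depth` and attribute `basis_corr`.
#' @export
simulate_correlated_counts <- function(n_taxa, n_samples, basis_corr,
                                       depth = 10000, seed = 1) {
  stopifnot(is.matrix(basis_corr),
            nrow(basis_corr) == n_taxa, ncol(basis_corr) == n_taxa)
  if (max(abs(basis_corr - t(basis_corr))) > 1e-8) {
    stop("basis_corr must be symmetric")
  }
  if (max(abs(diag(basis_corr) - 1)) > 1e-8) {
    stop("basis_corr must have unit diagonal")
  }
  L <- tryCatch(chol(basis_corr),
                error = function(e) stop("basis_corr must be positive-definite"))
  counts <- with_seed(seed, {
    mu <- stats::rnorm(n_taxa)
    z <- matrix(stats::rnorm(n_taxa * n_samples), n_taxa, n_samples)
    logx <- mu + crossprod(L, z)   # t(L) %*% z has covariance basis_corr
    vapply(seq_len(n_samples), function(s) {
      p <- exp(logx[, s] - max(logx[, s]))
      stats::rmultinom(1, depth, p / sum(p))[, 1]
    }, integer(n_taxa))
  })
  dimnames(counts) <- list(paste0("t", seq_len(n_taxa)),
                           sprintf("s%03d", seq_len(n_samples)))
  storage.mode(counts) <- "integer"
  attr(counts, "basis_corr") <- basis_corr
  counts
}

#' Simulate a full study mimic
#'
#' Convenience wrapper generating a tree, conserved niche traits, and a
#' group-structured community in one call; the defaults emulate a survey of
#' 54 samples in 4 groups (three vegetation types plus bulk soil) with a
#' large taxon pool filtered downstream to the abundant fraction.
#'
#' For selection scenarios the niche guild must be phylogenetically
#' coherent — that is the scenario's defining feature, and the premise the
#' phylogenetic null model tests. Trait histories are therefore redrawn (up
#' to `max_trait_tries` sub-seeds) until the placed optimum's guild has a
#' tightness ratio of at most `tightness_max`; if none qualifies the
#' tightest draw is used with a warning.
#'
#' @param seed Integer root seed (split across tree, traits, community).
#' @param n_taxa,n_samples,n_groups,depth Study dimensions.
#' @param scenario Assembly scenario (default heterogeneous selection:
#'   contrasting environmental filters across groups).
#' @param conservatism Trait conservatism passed to [evolve_trait()].
#' @param max_trait_tries,tightness_max Scenario-realization search for the
#'   selection scenarios (see Details).
#' @param ... Passed to [scenario_config()].
#' @return List with `counts`, `metadata`, `tree`, `traits`, `config`.
#' @export
simulate_study <- function(seed = 1, n_taxa = 2000, n_samples = 54,
                           n_groups = 4, depth = 20000,
                           scenario = "heterogeneous_selection",
                           conservatism = 0.2, max_trait_tries = 25,
                           tightness_max = 0.45, ...) {
  seeds <- split_seed(seed, 3)
  tree <- simulate_phylogeny(n_taxa, seed = seeds[1])
  config <- scenario_config(scenario, n_taxa = n_taxa, n_samples = n_samples,
                            n_groups = n_groups, depth = depth,
                            seed = seeds[3], ...)
  sel <- config$scenario %in% c("homogeneous_selection",
                                "heterogeneous_selection")
  if (sel) {
    tseeds <- split_seed(seeds[2], max_trait_tries)
    min_guild <- max(8, round(config$guild_frac * n_taxa / 3))
    best <- NULL
    for (k in seq_len(max_trait_tries)) {
      tr_k <- evolve_trait(tree, config$trait_sigma, seed = tseeds[k],
                           conservatism = conservatism)
      so <- select_optima(tree, tr_k, config)
      # a qualifying draw has coherent guilds of workable size; undersized
      # guilds give an unstable between-guild signal
      score <- so$tightness + 10 * (min(lengths(so$guilds)) < min_guild)
      if (is.null(best) || score < best$score) {
        best <- list(traits = tr_k, score = score)
      }
      if (score <= tightness_max) break
    }
    if (best$score > tightness_max) {
      warning("no trait draw realized a coherent niche guild ",
              "(best score ", signif(best$score, 3), "); using best draw")
    }
    traits <- best$traits
  } else {
    traits <- evolve_trait(tree, config$trait_sigma, seed = seeds[2],
                           conservatism = conservatism)
  }
  sim <- simulate_community(config, tree, traits)
  c(sim, list(tree = tree, traits = traits, config = config))
}
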
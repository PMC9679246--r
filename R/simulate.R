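#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. All simulators
#' are pure functions of `(tree, config)`: the seed is mandatory and
#' each generator draws from its own fixed offset of the seed stream,
#' so the same config always yields bit-identical output.
#'
#' Defaults emulate the study conditions of a fish comparative dataset:
#' about 60 species, 243 pure TSGs and 243 pure OGs, duplication and
#' loss rates giving normalized counts around 1.5--2.2 copies per found
#' gene, a strong (0.95) lineage-driven correlation between normalized
#' TSG and OG counts, and a lifespan signal carried by the TSG-OG
#' balance that is masked in marginal models.
#'
#' @param seed integer seed (mandatory).
#' @param n_taxa number of species (>= 3).
#' @param birth_rate Yule speciation rate.
#' @param n_tsg,n_og gene-set sizes.
#' @param duplication_rate,loss_rate per-copy, per-unit-depth birth and
#'   death rates of the copy-number process.
#' @param rate_sigma SD (per unit depth) of the Brownian
#'   log-duplication-rate field; partitioned into a component shared by
#'   TSGs and OGs and set-specific components by `tsg_og_corr`.
#' @param rate_clamp bound on the log-rate field: the field is clamped
#'   to `[-rate_clamp, rate_clamp]` so lineage duplication rates stay
#'   within a factor `exp(rate_clamp)` of the baseline and the copy
#'   process cannot become explosive.
#' @param tsg_og_corr target correlation of normalized TSG and OG
#'   counts across species, in (-1, 1); the shared variance fraction of
#'   the rate field.
#' @param wgd_lineages list of character vectors; each vector names the
#'   tips of a clade whose copy counts are doubled at the clade stem
#'   (whole-genome duplication). When empty, `n_wgd_clades` clades are
#'   auto-selected from the simulated tree.
#' @param n_wgd_clades number of WGD clades to auto-select when
#'   `wgd_lineages` is empty (default 2, emulating the salmonid and
#'   cyprinid genome duplications); clade sizes are drawn from
#'   `wgd_clade_size`. Set to 0 for a WGD-free dataset.
#' @param wgd_clade_size `c(min, max)` tip-count range for auto-selected
#'   WGD clades.
#' @param wgd_multiplier copy multiplier at a WGD stem (default 2).
#' @param wgd_families family labels assigned to WGD clades in the
#'   trait table (recycled).
#' @param mask_frac fraction of gene-species pairs masked as not-found.
#' @param mask_mode `"mcar"` (missing completely at random) or
#'   `"lineage"` (per-species masking probabilities drawn uniformly in
#'   `[0, 2 * mask_frac]`, stressing the normalization).
#' @param gatekeeper_frac fraction of TSGs labelled gatekeeper.
#' @param beta_bodysize regression effect of log10 body length on log10
#'   lifespan.
#' @param beta_ratio effect of the standardized TSG-OG contrast on
#'   log10 lifespan, in units of the residual SD.
#' @param resid_sigma SD of the Brownian lifespan residual (log10
#'   years).
#' @param true_lambda,true_kappa,true_delta transform values under
#'   which Brownian residuals are generated.
#' @param length_mean_log10,length_sigma mean and Brownian SD of log10
#'   body length (cm).
#' @param lifespan_intercept intercept of the log10 lifespan model.
#' @param low_quality_frac fraction of species flagged with low-quality
#'   trait sources.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_taxa = 60L,
                       birth_rate = 1,
                       n_tsg = 243L,
                       n_og = 243L,
                       duplication_rate = 0.08,
                       loss_rate = 0.13,
                       rate_sigma = 1.2,
                       rate_clamp = 1.5,
                       tsg_og_corr = 0.95,
                       wgd_lineages = list(),
                       n_wgd_clades = 2L,
                       wgd_clade_size = c(3L, 6L),
                       wgd_multiplier = 2L,
                       wgd_families = c("salmonidae", "cyprinidae"),
                       mask_frac = 0.05,
                       mask_mode = c("mcar", "lineage"),
                       gatekeeper_frac = 0.6,
                       beta_bodysize = 0.35,
                       beta_ratio = 1,
                       resid_sigma = 0.15,
                       true_lambda = 1,
                       true_kappa = 1,
                       true_delta = 1,
                       length_mean_log10 = 1.6,
                       length_sigma = 0.4,
                       lifespan_intercept = 0.55,
                       low_quality_frac = 0.15) {
  if (missing(seed)) stop("seed is mandatory (no implicit entropy)")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  stopifnot(birth_rate > 0, duplication_rate >= 0, loss_rate >= 0,
            rate_sigma >= 0, rate_clamp > 0, mask_frac >= 0, mask_frac < 1,
            resid_sigma > 0, true_lambda >= 0, true_lambda <= 1,
            true_kappa >= 0, true_delta > 0,
            gatekeeper_frac >= 0, gatekeeper_frac <= 1)
  if (tsg_og_corr <= -1 || tsg_og_corr >= 1)
    stop("tsg_og_corr must be in (-1, 1)")
  mask_mode <- match.arg(mask_mode)
  structure(as.list(environment()), class = "sim_config")
}

## seed-stream offsets per generator; keeps derived seeds below 2^31
.sim_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) + offset * 100003) %% 2147483647)
}

#' Simulate an ultrametric Yule species tree
#'
#' Pure-birth process started from two lineages at the root, with
#' Exp(k * birth_rate) waiting times while k lineages exist, stopped
#' uniformly within the n-lineage epoch and rescaled to unit
#' root-to-tip depth. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return an ultrametric `phylo` tree with tips `sp01, sp02, ...`.
#' @export
simulate_yule_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 0L))
  n <- as.integer(config$n_taxa)
  b <- config$birth_rate
  n_nodes <- 2L * n - 1L
  ## internal nodes n+1 .. 2n-1 in order of splitting; root = n + 1
  parent_of <- integer(n_nodes)
  start_time <- numeric(n_nodes)
  ## active lineages: ids of their (eventual) nodes; provisional ids
  ## assigned as internal until they either split or become tips
  active <- c(1L, 2L)                       # provisional lineage ids
  lin_parent <- c(n + 1L, n + 1L)           # parent internal node
  lin_start <- c(0, 0)
  next_internal <- n + 2L
  splits <- if (n > 2L) cumsum(stats::rexp(n - 2L, rate = b * (2:(n - 1L)))) else numeric(0)
  t_end <- (if (n > 2L) splits[n - 2L] else 0) + stats::rexp(1L, rate = b * n)
  edge <- matrix(0L, 0, 2)
  elen <- numeric(0)
  for (j in seq_along(splits)) {
    i <- sample.int(length(lin_start), 1L)
    node <- next_internal; next_internal <- next_internal + 1L
    edge <- rbind(edge, c(lin_parent[i], node))
    elen <- c(elen, splits[j] - lin_start[i])
    ## replace lineage i with two children of `node`
    lin_parent <- c(lin_parent[-i], node, node)
    lin_start <- c(lin_start[-i], splits[j], splits[j])
  }
  ## pendant edges to tips 1..n
  for (i in seq_along(lin_start)) {
    edge <- rbind(edge, c(lin_parent[i], i))
    elen <- c(elen, t_end - lin_start[i])
  }
  tree <- structure(list(edge = edge, edge.length = elen / t_end,
                         tip.label = sprintf("sp%02d", seq_len(n)),
                         Nnode = n - 1L),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Simulate Brownian-motion traits on a tree
#'
#' Draws one or more trait columns from a multivariate normal with
#' covariance `sigma^2 * V(kappa, delta, lambda)` built via
#' [transform_vcv()] at the config's true transform values.
#'
#' @param tree an ultrametric `phylo` tree.
#' @param config a [sim_config()].
#' @param sigma Brownian SD per unit depth.
#' @param n_traits number of independent trait columns.
#' @param seed_offset internal stream offset (distinct generators use
#'   distinct offsets).
#' @return matrix (species x traits) with tip labels as row names.
#' @export
simulate_bm_traits <- function(tree, config, sigma = 1, n_traits = 1L,
                               seed_offset = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  set.seed(.sim_seed(config, seed_offset))
  V <- transform_vcv(tree, kappa = config$true_kappa,
                     lambda = config$true_lambda,
                     delta = config$true_delta)
  n <- nrow(V)
  U <- chol(V + diag(1e-12 * mean(diag(V)), n))
  z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  x <- sigma * t(U) %*% z
  rownames(x) <- tree$tip.label
  x
}

## exact linear birth-death transition over a branch, vectorized over
## genes; per-copy rates dup/loss, absorbing at 0
.bd_branch <- function(counts, t, dup, loss) {
  if (dup + loss == 0 || t == 0) return(counts)
  remaining <- rep(t, length(counts))
  active <- which(counts > 0L)
  p_dup <- dup / (dup + loss)
  while (length(active)) {
    dt <- stats::rexp(length(active), rate = counts[active] * (dup + loss))
    ev <- dt < remaining[active]
    idx <- active[ev]
    if (!length(idx)) break
    remaining[idx] <- remaining[idx] - dt[ev]
    up <- stats::runif(length(idx)) < p_dup
    counts[idx] <- counts[idx] + ifelse(up, 1L, -1L)
    active <- idx[counts[idx] > 0L]
  }
  counts
}

#' Simulate gene copy counts along a tree
#'
#' Each gene starts at 2 copies at the root (the post-duplication
#' teleost baseline) and evolves by a linear birth-death process along
#' branches. The per-copy duplication rate on a branch is modulated by
#' a Brownian log-rate field with a component shared between the TSG
#' and OG sets (variance fraction `tsg_og_corr`) and set-specific
#' components: shared lineage duplication propensity is what generates
#' the strong cross-species correlation between normalized TSG and OG
#' counts. Clades listed in `wgd_lineages` have their copy state
#' multiplied at the clade stem (whole-genome duplication); a
#' configurable fraction of gene-species pairs is masked as not-found
#' to exercise the normalization.
#'
#' @param tree a `phylo` tree (tips are the species).
#' @param config a [sim_config()].
#' @return list with `table` (a `gene_count_table` with the not-found
#'   mask applied), `gene_roles` (data frame: gene, role, tsg_class),
#'   and `truth` (list: complete unmasked count matrix, found mask, and
#'   per-species true normalized values).
#' @export
simulate_gene_counts <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  set.seed(.sim_seed(config, 2L))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- ape::Ntip(tree)
  E <- nrow(tree$edge)
  el <- tree$edge.length
  d <- config$duplication_rate
  l <- config$loss_rate
  rho <- config$tsg_og_corr
  sig_sh <- config$rate_sigma * sqrt(abs(rho))
  sig_set <- config$rate_sigma * sqrt(1 - abs(rho))

  ## Brownian log-rate field at edge children: shared + per-set
  g_sh <- numeric(n + tree$Nnode)
  g_tsg <- numeric(n + tree$Nnode)
  g_og <- numeric(n + tree$Nnode)
  inc_sh <- stats::rnorm(E, 0, sig_sh * sqrt(el))
  inc_t <- stats::rnorm(E, 0, sig_set * sqrt(el))
  inc_o <- stats::rnorm(E, 0, sig_set * sqrt(el))
  for (e in seq_len(E)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    g_sh[ch] <- g_sh[p] + inc_sh[e]
    g_tsg[ch] <- g_tsg[p] + inc_t[e]
    g_og[ch] <- g_og[p] + inc_o[e]
  }
  ## complete per-set log-rate fields; a negative target correlation
  ## flips the sign of the shared component for the OG set. Clamped so
  ## the copy process stays subcritical.
  cl <- config$rate_clamp
  g_tsg <- pmin(pmax(g_sh + g_tsg, -cl), cl)
  g_og <- pmin(pmax(sign(rho) * g_sh + g_og, -cl), cl)

  ## resolve WGD clades: explicit tip sets, or seeded auto-selection of
  ## non-overlapping clades within the configured size range
  clades <- config$wgd_lineages
  if (!length(clades) && config$n_wgd_clades > 0L) {
    tips_of <- function(node) {
      if (node <= n) return(tree$tip.label[node])
      keep <- ape::extract.clade(tree, node)$tip.label
      keep
    }
    cand <- (n + 1L):(n + tree$Nnode)
    sizes <- vapply(cand, function(nd) length(tips_of(nd)), 1L)
    cand <- cand[sizes >= config$wgd_clade_size[1] &
                 sizes <= config$wgd_clade_size[2]]
    cand <- cand[sample.int(length(cand))]
    used <- character(0)
    for (nd in cand) {
      if (length(clades) >= config$n_wgd_clades) break
      tt <- tips_of(nd)
      if (!length(intersect(tt, used))) {
        clades <- c(clades, list(tt))
        used <- c(used, tt)
      }
    }
  }
  wgd_edges <- integer(0)
  for (tips in clades) {
    tips <- canonical_species(tips)
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss))
      stop("WGD clade tips absent from tree: ", paste(miss, collapse = ", "))
    node <- if (length(tips) == 1L) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) stop("WGD clade spans the root; no stem edge exists")
    wgd_edges <- c(wgd_edges, e)
  }

  sim_set <- function(n_genes, g_set) {
    states <- vector("list", n + tree$Nnode)
    root <- n + 1L
    states[[root]] <- rep(2L, n_genes)
    counts <- matrix(0L, n_genes, n)
    for (e in seq_len(E)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      st <- states[[p]]
      if (e %in% wgd_edges) st <- st * as.integer(config$wgd_multiplier)
      mult <- exp(g_set[ch])
      st <- .bd_branch(st, el[e], d * mult, l)
      if (ch <= n) counts[, ch] <- st else states[[ch]] <- st
    }
    counts
  }

  tsg_counts <- sim_set(config$n_tsg, g_tsg)
  og_counts <- sim_set(config$n_og, g_og)
  counts <- rbind(tsg_counts, og_counts)
  genes <- c(sprintf("tsg%03d", seq_len(config$n_tsg)),
             sprintf("og%03d", seq_len(config$n_og)))
  n_gk <- ceiling(config$gatekeeper_frac * config$n_tsg)
  gene_roles <- data.frame(
    gene = genes,
    role = rep(c("TSG", "oncogene"), c(config$n_tsg, config$n_og)),
    tsg_class = c(rep(c("gatekeeper", "caretaker"),
                      c(n_gk, config$n_tsg - n_gk)),
                  rep("unknown", config$n_og)),
    stringsAsFactors = FALSE)

  ## not-found mask
  G <- nrow(counts)
  if (config$mask_mode == "mcar") {
    found <- matrix(stats::runif(G * n) >= config$mask_frac, G, n)
  } else {
    p_sp <- stats::runif(n, 0, 2 * config$mask_frac)
    found <- matrix(stats::runif(G * n), G, n) >=
      matrix(p_sp, G, n, byrow = TRUE)
  }
  masked <- counts
  masked[!found] <- 0L
  table <- new_gene_count_table(masked, found, genes, tree$tip.label)

  truth <- list(
    counts = `dimnames<-`(counts, list(genes, tree$tip.label)),
    found = `dimnames<-`(found, list(genes, tree$tip.label)),
    norm_tsg_true = colMeans(tsg_counts),
    norm_og_true = colMeans(og_counts))
  list(table = table, gene_roles = gene_roles, truth = truth,
       wgd_tips = clades)
}

#' CAFE-style gene trees from a count table
#'
#' Encodes each gene's per-species counts as a Newick string on the
#' species-tree topology: leaves are relabelled `species_count` and
#' species with `found = FALSE` are pruned (missing from the gene
#' tree, as distinct from count 0).
#'
#' @param tree the species `phylo` tree.
#' @param table a `gene_count_table` over the same species.
#' @return named character vector of Newick strings (one per gene);
#'   genes found in fewer than 2 species yield `NA`.
#' @export
cafe_gene_trees <- function(tree, table) {
  stopifnot(inherits(tree, "phylo"), inherits(table, "gene_count_table"))
  stopifnot(all(table$species %in% tree$tip.label))
  out <- stats::setNames(rep(NA_character_, length(table$genes)), table$genes)
  for (i in seq_along(table$genes)) {
    sp <- table$species[table$found[i, ]]
    if (length(sp) < 2L) next
    gt <- prune_to_taxa(tree, sp)
    cc <- table$counts[i, match(gt$tip.label, table$species)]
    gt$tip.label <- paste0(gt$tip.label, "_", cc)
    out[i] <- write_newick(gt)
  }
  out
}

#' Simulate life-history traits with a masked TSG/OG-lifespan effect
#'
#' Body length is a Brownian trait; log10 maximum lifespan is
#' `intercept + beta_bodysize * log10(length) +
#'  beta_ratio * resid_sigma * (z_tsg - z_og) / sd(z_tsg - z_og) +
#'  Brownian residual`.
#' Because normalized TSG and OG counts are strongly correlated, the
#' marginal association of each with lifespan is attenuated while the
#' contrast (equivalently, the TSG/OG ratio) carries the full signal:
#' the masked-relationship structure. The effect size `beta_ratio` is
#' expressed in residual-SD units of the standardized contrast. Body
#' mass follows the cubic length-mass allometry `0.01 * length^3` g.
#'
#' @param tree the species tree.
#' @param norm a [normalized_counts()] data frame (or the output of
#'   [simulate_gene_counts()] passed through it).
#' @param config a [sim_config()].
#' @param wgd_tips list of tip sets of the realized WGD clades (used
#'   only for family labels in the trait table); defaults to the
#'   config's explicit `wgd_lineages`.
#' @return trait data frame (see [validate_traits()]) over the species
#'   of `norm`.
#' @export
simulate_masked_lifespan <- function(tree, norm, config,
                                     wgd_tips = config$wgd_lineages) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(norm))
  species <- norm$species
  tree <- prune_to_taxa(tree, species)
  norm <- norm[match(tree$tip.label, norm$species), , drop = FALSE]

  loglen <- config$length_mean_log10 +
    simulate_bm_traits(tree, config, sigma = config$length_sigma,
                       seed_offset = 3L)[, 1]
  resid <- simulate_bm_traits(tree, config, sigma = config$resid_sigma,
                              seed_offset = 4L)[, 1]
  contrast <- norm$z_tsg - norm$z_og
  sdc <- stats::sd(contrast)
  std_contrast <- if (is.finite(sdc) && sdc > 0) contrast / sdc else contrast * 0
  loglife <- config$lifespan_intercept +
    config$beta_bodysize * loglen +
    config$beta_ratio * config$resid_sigma * std_contrast +
    resid

  set.seed(.sim_seed(config, 5L))
  n <- length(species)
  quality <- ifelse(stats::runif(n) < config$low_quality_frac, "low", "reliable")
  family <- rep("other", n)
  if (length(wgd_tips)) {
    fam_names <- rep_len(config$wgd_families, length(wgd_tips))
    for (i in seq_along(wgd_tips)) {
      family[tree$tip.label %in% canonical_species(wgd_tips[[i]])] <-
        fam_names[i]
    }
  }
  len <- 10^loglen
  validate_traits(data.frame(
    species = tree$tip.label,
    max_length_cm = len,
    max_lifespan_y = 10^loglife,
    body_mass_g = 0.01 * len^3,
    source_quality = quality,
    family = family,
    stringsAsFactors = FALSE))
}

#' Simulate a complete analysis dataset
#'
#' Orchestrates [simulate_yule_tree()], [simulate_gene_counts()],
#' [normalized_counts()] and [simulate_masked_lifespan()] into one
#' seeded bundle mirroring the external inputs of the pipeline.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `counts` (the [simulate_gene_counts()]
#'   result), `normalized`, `traits`, and `config`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_yule_tree(config)
  counts <- simulate_gene_counts(tree, config)
  subsets <- list(
    tsg = counts$gene_roles$gene[counts$gene_roles$role == "TSG"],
    og = counts$gene_roles$gene[counts$gene_roles$role == "oncogene"],
    gatekeeper = counts$gene_roles$gene[counts$gene_roles$tsg_class == "gatekeeper"],
    caretaker = counts$gene_roles$gene[counts$gene_roles$tsg_class == "caretaker"])
  norm <- normalized_counts(counts$table, subsets)
  traits <- simulate_masked_lifespan(tree, norm, config,
                                     wgd_tips = counts$wgd_tips)
  list(tree = tree, counts = counts, normalized = norm,
       traits = traits, config = config)
}

#' Write a simulated dataset as an on-disk fixture bundle
#'
#' Emits exactly the external formats the ingestion functions read:
#' `species_tree.nwk`, `gene_trees.nwk` + `gene_map.tsv`,
#' `counts.tsv` + `found.tsv`, `traits.csv`, a COSMIC-style
#' `census.csv` + `gatekeepers.tsv`, and `ground_truth.json`.
#'
#' @param bundle a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  writeLines(write_newick(bundle$tree), fp("species_tree.nwk"))

  gt <- cafe_gene_trees(bundle$tree, bundle$counts$table)
  ok <- !is.na(gt)
  writeLines(unname(gt[ok]), fp("gene_trees.nwk"))
  utils::write.table(data.frame(line = seq_len(sum(ok)), gene = names(gt)[ok]),
                     fp("gene_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_count_table(bundle$counts$table, fp("counts.tsv"), fp("found.tsv"))
  utils::write.csv(bundle$traits, fp("traits.csv"), row.names = FALSE)

  roles <- bundle$counts$gene_roles
  utils::write.csv(data.frame(gene = roles$gene, role = roles$role,
                              tier = 1L, somatic = "yes", germline = "no"),
                   fp("census.csv"), row.names = FALSE)
  gk <- roles[roles$tsg_class != "unknown", c("gene", "tsg_class")]
  names(gk) <- c("gene", "class")
  utils::write.table(gk, fp("gatekeepers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jsonlite::write_json(
    list(seed = bundle$config$seed,
         species = bundle$tree$tip.label,
         norm_tsg_true = unname(bundle$counts$truth$norm_tsg_true),
         norm_og_true = unname(bundle$counts$truth$norm_og_true),
         counts_true = bundle$counts$truth$counts),
    fp("ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
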
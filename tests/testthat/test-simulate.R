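test_that("sim_config validates its knobs and requires a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_taxa = 2), "n_taxa")
  expect_error(sim_config(seed = 1, tsg_og_corr = 1), "tsg_og_corr")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_tsg, 243L)
  expect_equal(cfg$n_og, 243L)
})

test_that("derived seed streams stay below 2^31 and differ across offsets", {
  cfg <- sim_config(seed = 2147483646)
  seeds <- vapply(0:6, function(o) oncophylo:::.sim_seed(cfg, o), 1L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("simulate_yule_tree is deterministic, ultrametric and unit depth", {
  cfg <- sim_config(seed = 17, n_taxa = 25)
  t1 <- simulate_yule_tree(cfg)
  t2 <- simulate_yule_tree(cfg)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_equal(ape::Ntip(t1), 25L)
  expect_true(is_ultrametric_tree(t1))
  d <- node_depths(t1)
  expect_equal(unname(d[seq_len(25)]), rep(1, 25), tolerance = 1e-9)

  t3 <- simulate_yule_tree(sim_config(seed = 18, n_taxa = 25))
  expect_false(identical(write_newick(t1), write_newick(t3)))
})

test_that("BM traits have the phylogenetic covariance structure", {
  cfg <- sim_config(seed = 21, n_taxa = 20)
  tr <- simulate_yule_tree(cfg)
  X <- simulate_bm_traits(tr, cfg, sigma = 1, n_traits = 400, seed_offset = 7)
  expect_equal(dim(X), c(20L, 400L))
  V <- phylo_vcv(tr)
  S <- tcrossprod(X) / ncol(X)
  # empirical covariance converges to V; Monte Carlo tolerance
  expect_lt(max(abs(S - V)), 0.35)
  expect_lt(mean(abs(S - V)), 0.08)
})

test_that("simulate_gene_counts is deterministic and found/not-found is honored", {
  cfg <- sim_config(seed = 23, n_taxa = 20, n_tsg = 40, n_og = 40)
  tr <- simulate_yule_tree(cfg)
  s1 <- simulate_gene_counts(tr, cfg)
  s2 <- simulate_gene_counts(tr, cfg)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$table$found, s2$table$found)

  # masked cells hold zero and are flagged not-found; truth is complete
  expect_true(all(s1$table$counts[!s1$table$found] == 0L))
  expect_true(all(s1$table$counts >= 0))
  expect_equal(dim(s1$truth$counts), dim(s1$table$counts))
  expect_true(all(s1$truth$counts[s1$table$found] ==
                    s1$table$counts[s1$table$found]))

  # mask fraction close to the configured MCAR rate
  expect_lt(abs(mean(!s1$table$found) - cfg$mask_frac), 0.02)

  # roles cover the configured set sizes
  expect_equal(sum(s1$gene_roles$role == "TSG"), 40L)
  expect_equal(sum(s1$gene_roles$tsg_class == "gatekeeper"),
               ceiling(0.6 * 40))
})

test_that("WGD clades roughly double normalized counts but leave the ratio in line", {
  cfg <- sim_config(seed = 29, n_taxa = 40, n_tsg = 60, n_og = 60,
                    mask_frac = 0)
  tr <- simulate_yule_tree(cfg)
  s <- simulate_gene_counts(tr, cfg)
  expect_equal(length(s$wgd_tips), 2L)
  wgd <- unlist(s$wgd_tips)
  bg <- setdiff(tr$tip.label, wgd)
  nt <- s$truth$norm_tsg_true
  names(nt) <- tr$tip.label
  expect_gt(mean(nt[wgd]) / mean(nt[bg]), 1.5)

  # ratio is WGD-invariant by construction
  no <- s$truth$norm_og_true
  names(no) <- tr$tip.label
  r <- nt / no
  expect_lt(abs(mean(r[wgd]) - mean(r[bg])), 0.25)
})

test_that("explicit WGD lineages are honored and missing tips rejected", {
  cfg0 <- sim_config(seed = 31, n_taxa = 12, n_tsg = 20, n_og = 20,
                     n_wgd_clades = 0L)
  tr <- simulate_yule_tree(cfg0)
  s0 <- simulate_gene_counts(tr, cfg0)
  expect_equal(length(s0$wgd_tips), 0L)

  pair <- ape::extract.clade(tr, ape::getMRCA(tr, tr$tip.label[1:2]))$tip.label
  cfg1 <- sim_config(seed = 31, n_taxa = 12, n_tsg = 20, n_og = 20,
                     wgd_lineages = list(tr$tip.label[1]))
  s1 <- simulate_gene_counts(tr, cfg1)
  expect_equal(s1$wgd_tips[[1]], tr$tip.label[1])

  cfgbad <- sim_config(seed = 31, n_taxa = 12,
                       wgd_lineages = list(c("nonexistent_sp")))
  expect_error(simulate_gene_counts(tr, cfgbad), "nonexistent_sp")
})

test_that("cafe_gene_trees encodes counts and prunes not-found species", {
  cfg <- sim_config(seed = 37, n_taxa = 10, n_tsg = 5, n_og = 5,
                    mask_frac = 0.2)
  tr <- simulate_yule_tree(cfg)
  s <- simulate_gene_counts(tr, cfg)
  gts <- cafe_gene_trees(tr, s$table)
  for (g in names(gts)) {
    if (is.na(gts[[g]])) next
    cc <- extract_cafe_counts(gts[[g]])
    sp_found <- s$table$species[s$table$found[g, ]]
    expect_setequal(names(cc), sp_found)
    expect_equal(unname(cc[sp_found]),
                 unname(s$table$counts[g, sp_found]))
  }
  # round trip: gene trees -> count table recovers the masked table
  ok <- !is.na(gts)
  tab2 <- counts_from_gene_trees(as.list(gts[ok]), s$table$species)
  expect_equal(tab2$counts[names(gts)[ok], ], s$table$counts[ok, ])
  expect_equal(tab2$found[names(gts)[ok], ], s$table$found[ok, ])
})

test_that("masked lifespan carries the contrast effect with masked marginals", {
  b <- small_bundle(seed = 41, n_taxa = 50)
  tr <- b$traits
  expect_s3_class(tr, "data.frame")
  expect_setequal(tr$species, b$tree$tip.label)
  expect_true(all(tr$max_lifespan_y > 0))
  expect_equal(tr$body_mass_g, 0.01 * tr$max_length_cm^3, tolerance = 1e-9)
  # WGD clades are labelled with the configured family names
  wgd <- unlist(b$counts$wgd_tips)
  expect_true(all(tr$family[tr$species %in% wgd] %in%
                    c("salmonidae", "cyprinidae")))
  expect_true(all(tr$family[!tr$species %in% wgd] == "other"))
})

test_that("simulate_dataset is reproducible end to end", {
  b1 <- small_bundle(seed = 43, n_taxa = 25)
  b2 <- small_bundle(seed = 43, n_taxa = 25)
  expect_identical(b1$counts$table$counts, b2$counts$table$counts)
  expect_equal(b1$traits$max_lifespan_y, b2$traits$max_lifespan_y)
  expect_equal(b1$normalized$ratio_tsg_og, b2$normalized$ratio_tsg_og)
})

test_that("fixture bundle round-trips through the ingestion functions", {
  dir <- withr::local_tempdir()
  b <- small_bundle(seed = 47, n_taxa = 12, n_tsg = 15, n_og = 15)
  write_fixture_bundle(b, dir)

  tr <- read_newick(readLines(file.path(dir, "species_tree.nwk")))
  expect_setequal(tr$tip.label, b$tree$tip.label)

  tab <- read_count_table(file.path(dir, "counts.tsv"),
                          file.path(dir, "found.tsv"))
  expect_equal(tab$counts, b$counts$table$counts)
  expect_equal(tab$found, b$counts$table$found)

  gts <- read_gene_trees(file.path(dir, "gene_trees.nwk"),
                         file.path(dir, "gene_map.tsv"))
  tab2 <- counts_from_gene_trees(gts, tr$tip.label)
  common <- intersect(rownames(tab2$counts), rownames(tab$counts))
  expect_equal(tab2$counts[common, tab$species],
               tab$counts[common, tab$species])

  traits <- read_traits(file.path(dir, "traits.csv"))
  expect_equal(traits$max_lifespan_y, b$traits$max_lifespan_y,
               tolerance = 1e-9)

  census <- read_cosmic_census(file.path(dir, "census.csv"))
  cl <- classify_cosmic(census,
                        read_gatekeeper_list(file.path(dir, "gatekeepers.tsv")))
  s <- gene_subsets(cl)
  expect_setequal(s$tsg, b$counts$gene_roles$gene[b$counts$gene_roles$role == "TSG"])
})

test_that("generator calibration: realized TSG-OG correlation near the target", {
  # single-seed sanity check at study size; the multi-replicate check
  # lives in the acceptance suite
  b <- small_bundle(seed = 53, n_taxa = 60)
  r <- cor(b$normalized$norm_tsg, b$normalized$norm_og)
  expect_gt(r, 0.85)
})
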
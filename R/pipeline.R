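#' Assemble an aligned analysis dataset
#'
#' Intersection join, on canonical species names, of the species tree,
#' the normalized count table and the trait table. Every dropped
#' species is logged with a reason code (`absent_from_tree`,
#' `absent_from_counts`, `absent_from_traits`, `no_lifespan`,
#' `family_excluded`, `low_quality`); subset rules implement the
#' sensitivity analyses (dropping whole-genome-duplicated families,
#' keeping only reliably sourced trait rows).
#'
#' Z-score columns are carried over from [normalized_counts()] -- the
#' standardization set is all species surviving ingestion there, not
#' recomputed per subset.
#'
#' @param tree species `phylo` tree.
#' @param norm a [normalized_counts()] data frame.
#' @param traits a trait data frame (see [validate_traits()]).
#' @param subset_rules list with optional elements `drop_families`
#'   (character), `reliable_only` (logical), `require_lifespan`
#'   (logical, default TRUE).
#' @return object of class `cgc_dataset`: list with `tree` (pruned),
#'   `data` (aligned data frame with log10 traits, LQ when body mass
#'   allows it, normalized counts, z-scores and ratio), `exclusions`
#'   (data frame species/reason), `n`.
#' @export
build_dataset <- function(tree, norm, traits,
                          subset_rules = list()) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(norm))
  traits <- validate_traits(traits)
  rules <- utils::modifyList(
    list(drop_families = character(0), reliable_only = FALSE,
         require_lifespan = TRUE), subset_rules)

  excl <- data.frame(species = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  note <- function(sp, why) {
    if (length(sp)) rbind(excl, data.frame(species = sp, reason = why,
                                           stringsAsFactors = FALSE))
    else excl
  }
  universe <- union(union(norm$species, traits$species), tree$tip.label)
  excl <- note(setdiff(universe, tree$tip.label), "absent_from_tree")
  excl <- note(setdiff(universe, norm$species), "absent_from_counts")
  excl <- note(setdiff(universe, traits$species), "absent_from_traits")
  keep <- Reduce(intersect, list(tree$tip.label, norm$species, traits$species))

  tr <- traits[keep, , drop = FALSE]
  if (rules$require_lifespan) {
    drop <- keep[!is.finite(tr$max_lifespan_y)]
    excl <- note(drop, "no_lifespan")
    keep <- setdiff(keep, drop)
  }
  if (length(rules$drop_families)) {
    fam <- tolower(traits[keep, "family"])
    drop <- keep[fam %in% tolower(rules$drop_families)]
    excl <- note(drop, "family_excluded")
    keep <- setdiff(keep, drop)
  }
  if (isTRUE(rules$reliable_only)) {
    drop <- keep[traits[keep, "source_quality"] != "reliable"]
    excl <- note(drop, "low_quality")
    keep <- setdiff(keep, drop)
  }
  if (length(keep) < 3L)
    stop("fewer than 3 species survive the intersection join")

  tree <- prune_to_taxa(tree, keep)
  keep <- tree$tip.label
  df <- cbind(
    traits[keep, c("species", "max_length_cm", "max_lifespan_y",
                   "body_mass_g", "source_quality", "family")],
    norm[match(keep, norm$species),
         setdiff(names(norm), "species"), drop = FALSE])
  df$log10_length <- log10_transform(stats::setNames(df$max_length_cm, keep))
  df$log10_lifespan <- log10(df$max_lifespan_y)
  df$lq <- tryCatch(unname(longevity_quotient(traits)[keep]),
                    error = function(e) rep(NA_real_, length(keep)))
  rownames(df) <- keep
  structure(list(tree = tree, data = df, exclusions = excl,
                 n = length(keep)),
            class = "cgc_dataset")
}

#' @export
print.cgc_dataset <- function(x, ...) {
  cat("Aligned comparative dataset:", x$n, "species;",
      nrow(x$exclusions), "exclusion record(s)\n")
  invisible(x)
}

## the battery's model specifications; `main` models enter the
## Bonferroni count, diagnostics do not
.battery_models <- function(data) {
  specs <- list(
    lifespan_vs_bodysize = list(
      formula = log10_lifespan ~ log10_length, main = TRUE),
    tsg_vs_og = list(formula = z_tsg ~ z_og, main = TRUE),
    gatekeeper_vs_og = list(formula = z_gatekeeper ~ z_og, main = TRUE),
    caretaker_vs_og = list(formula = z_caretaker ~ z_og, main = TRUE),
    lifespan_vs_bodysize_ratio = list(
      formula = log10_lifespan ~ log10_length + ratio_tsg_og, main = TRUE),
    lifespan_vs_tsg_marginal = list(
      formula = log10_lifespan ~ z_tsg, main = FALSE),
    lifespan_vs_og_marginal = list(
      formula = log10_lifespan ~ z_og, main = FALSE))
  ok <- vapply(specs, function(s)
    all(all.vars(s$formula) %in% names(data)) &&
      all(vapply(all.vars(s$formula),
                 function(v) any(is.finite(data[[v]])), TRUE)),
    TRUE)
  specs[ok]
}

#' Run the comparative model battery
#'
#' Fits the study's model set -- (1) log lifespan ~ log body length,
#' (2) z TSG ~ z OG, (3) z gatekeeper ~ z OG, (4) z caretaker ~ z OG,
#' (5) log lifespan ~ log body length + TSG/OG ratio -- in fixed-
#' transform (kappa = lambda = delta = 1) and/or ML-optimized variants,
#' plus two diagnostic marginal models (lifespan ~ z TSG alone, and
#' ~ z OG alone) that exhibit the masking: the lifespan signal appears
#' only when both counts enter jointly or as a ratio.
#'
#' The Bonferroni threshold uses `alpha` divided by the number of main
#' model fits actually performed (model x variant; diagnostics are
#' excluded as redundant). Individual model failures are reported
#' per-model without aborting the battery.
#'
#' @param dataset a [build_dataset()] result.
#' @param variants subset of `c("fixed", "ML")`.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param which transforms optimized in the ML variant.
#' @return object of class `cgc_battery`: list with `results` (tidy
#'   data frame: model, variant, term, estimate, se, t, p, r_squared,
#'   log_likelihood, kappa, lambda, delta, n, main, significant),
#'   `m_tests`, `threshold`, `errors` (named list of per-model failure
#'   messages), `fits`.
#' @export
run_model_battery <- function(dataset, variants = c("fixed", "ML"),
                              alpha = 0.05,
                              which = c("kappa", "lambda", "delta")) {
  stopifnot(inherits(dataset, "cgc_dataset"))
  variants <- match.arg(variants, c("fixed", "ML"), several.ok = TRUE)
  specs <- .battery_models(dataset$data)
  rows <- list()
  fits <- list()
  errors <- list()
  for (nm in names(specs)) {
    for (variant in variants) {
      key <- paste(nm, variant, sep = ".")
      fit <- tryCatch(
        pgls(specs[[nm]]$formula, dataset$data, dataset$tree,
             method = if (variant == "ML") "ML" else "fixed",
             which = which),
        error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        errors[[key]] <- fit
        next
      }
      fits[[key]] <- fit
      tr <- fit$transforms
      rows[[key]] <- data.frame(
        model = nm, variant = variant,
        term = names(fit$coefficients),
        estimate = unname(fit$coefficients), se = unname(fit$se),
        t = unname(fit$t_values), p = unname(fit$p_values),
        r_squared = fit$r_squared, log_likelihood = fit$log_likelihood,
        kappa = tr$kappa, lambda = tr$lambda, delta = tr$delta,
        n = fit$n, main = specs[[nm]]$main,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  fitted_main <- unique(paste(results$model, results$variant)[results$main])
  m <- length(fitted_main)
  thr <- if (m >= 1) bonferroni_threshold(alpha, m) else NA_real_
  if (!is.null(results))
    results$significant <- results$main & results$p <= thr
  structure(list(results = results, m_tests = m, threshold = thr,
                 alpha = alpha, errors = errors, fits = fits),
            class = "cgc_battery")
}

#' @export
print.cgc_battery <- function(x, digits = 4, ...) {
  cat("Model battery:", x$m_tests, "main tests; Bonferroni threshold",
      signif(x$threshold, 3), "\n")
  df <- x$results
  df$estimate <- signif(df$estimate, digits)
  df$se <- signif(df$se, digits)
  df$t <- signif(df$t, digits)
  df$p <- signif(df$p, digits)
  print(df[, c("model", "variant", "term", "estimate", "se", "t", "p",
               "r_squared", "n", "significant")], row.names = FALSE)
  if (length(x$errors)) {
    cat("Models not fitted:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Rank species by TSG/OG ratio
#'
#' Species sorted by descending normalized TSG/OG ratio; ties broken
#' lexicographically and flagged. The ratio compensates for lineage
#' whole-genome duplications, so polyploid and diploid lineages are
#' comparable.
#'
#' @param dataset a [build_dataset()] result (or any data frame with
#'   `species` and `ratio_tsg_og` columns).
#' @param top_k how many species to flag at each extreme.
#' @return data frame: species, ratio_tsg_og, ratio_3dp (rounded for
#'   reporting), rank, tied, group (`"top"`, `"bottom"` or `""`).
#' @export
rank_species_by_ratio <- function(dataset, top_k = 5L) {
  df <- if (inherits(dataset, "cgc_dataset")) dataset$data else dataset
  stopifnot(all(c("species", "ratio_tsg_og") %in% names(df)))
  ord <- order(-df$ratio_tsg_og, df$species)
  out <- data.frame(species = df$species[ord],
                    ratio_tsg_og = df$ratio_tsg_og[ord],
                    stringsAsFactors = FALSE)
  out$ratio_3dp <- round(out$ratio_tsg_og, 3)
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$ratio_tsg_og) |
    duplicated(out$ratio_tsg_og, fromLast = TRUE)
  out$group <- ""
  k <- min(top_k, nrow(out))
  out$group[seq_len(k)] <- "top"
  out$group[seq(nrow(out) - k + 1L, nrow(out))] <- "bottom"
  rownames(out) <- NULL
  out
}
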
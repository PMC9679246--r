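#' Classify COSMIC-style cancer gene records by role
#'
#' Parses a table of cancer gene census records into role sets and
#' partitions genes into mutually exclusive categories:
#' \describe{
#'   \item{pure_tsg / pure_og / pure_fusion}{exactly one role}
#'   \item{both}{TSG and oncogene, no fusion}
#'   \item{all}{TSG, oncogene and fusion}
#'   \item{tsg_fusion / og_fusion}{one driver role plus fusion}
#'   \item{unclassified}{empty or unrecognized role string (kept and
#'     reported, never silently dropped)}
#' }
#' Genes carrying both the TSG and oncogene roles are excluded from TSG
#' and OG copy tallies downstream (see [gene_subsets()]).
#'
#' @param records data frame with columns `gene`, `role` (comma- or
#'   semicolon-separated list of "TSG", "oncogene", "fusion",
#'   case-insensitive), `tier` (1 or 2), and optionally `somatic`,
#'   `germline` flags.
#' @param gatekeepers optional data frame (`gene`, `class`) assigning
#'   TSGs to the gatekeeper or caretaker class; unlisted TSGs get class
#'   `"unknown"`.
#' @return object of class `gene_classification`: list with `genes`
#'   (per-gene data frame: gene, is_tsg, is_og, is_fusion, tier,
#'   category, tsg_class) and `tallies` (named integer vector over
#'   categories).
#' @export
classify_cosmic <- function(records, gatekeepers = NULL) {
  stopifnot(is.data.frame(records), all(c("gene", "role", "tier") %in% names(records)))
  tier <- as.integer(records$tier)
  if (any(!tier %in% c(1L, 2L)))
    stop("tier must be 1 or 2")
  role <- tolower(as.character(records$role))
  tokens <- strsplit(role, "[,;]")
  has <- function(tok, what) any(grepl(what, trimws(tok)))
  is_tsg <- vapply(tokens, has, TRUE, what = "^tsg$")
  is_og <- vapply(tokens, has, TRUE, what = "^(oncogene|og)$")
  is_fus <- vapply(tokens, has, TRUE, what = "^fusion$")
  category <- rep("unclassified", length(role))
  category[is_tsg & is_og & is_fus] <- "all"
  category[is_tsg & is_og & !is_fus] <- "both"
  category[is_tsg & !is_og & is_fus] <- "tsg_fusion"
  category[!is_tsg & is_og & is_fus] <- "og_fusion"
  category[is_tsg & !is_og & !is_fus] <- "pure_tsg"
  category[!is_tsg & is_og & !is_fus] <- "pure_og"
  category[!is_tsg & !is_og & is_fus] <- "pure_fusion"
  n_unc <- sum(category == "unclassified")
  if (n_unc > 0)
    message(n_unc, " gene(s) with empty/unrecognized role strings routed to 'unclassified'")

  tsg_class <- rep("unknown", length(role))
  if (!is.null(gatekeepers)) {
    stopifnot(is.data.frame(gatekeepers), all(c("gene", "class") %in% names(gatekeepers)))
    cls <- tolower(gatekeepers$class)
    if (any(!cls %in% c("gatekeeper", "caretaker")))
      stop("gatekeeper classes must be 'gatekeeper' or 'caretaker'")
    idx <- match(records$gene, gatekeepers$gene)
    tsg_class[!is.na(idx)] <- cls[idx[!is.na(idx)]]
  }
  tsg_class[!is_tsg] <- "unknown"  # class only meaningful for TSGs

  genes <- data.frame(
    gene = as.character(records$gene), is_tsg = is_tsg, is_og = is_og,
    is_fusion = is_fus, tier = tier, category = category,
    tsg_class = tsg_class, stringsAsFactors = FALSE
  )
  cats <- c("pure_tsg", "pure_og", "both", "all", "pure_fusion",
            "tsg_fusion", "og_fusion", "unclassified")
  tallies <- vapply(cats, function(cc) sum(category == cc), 0L)
  structure(list(genes = genes, tallies = tallies),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("Cancer gene classification:", nrow(x$genes), "genes\n")
  print(x$tallies)
  invisible(x)
}

#' Gene subsets used for copy-number tallies
#'
#' Returns the gene symbols entering each normalized count. Strict
#' pure-role counting is the default: only `pure_tsg` genes count as
#' TSGs and only `pure_og` genes as OGs; genes classified as both TSG
#' and oncogene are always excluded. With `include_fusion_mixed = TRUE`,
#' TSG+fusion and OG+fusion genes are added to the respective subsets.
#'
#' @param classification a [classify_cosmic()] result.
#' @param tiers tiers to keep (default `c(1, 2)`; use `1` for the
#'   tier-1-only analysis).
#' @param include_fusion_mixed logical, see Description.
#' @return list with character vectors `tsg`, `og`, `gatekeeper`,
#'   `caretaker`.
#' @export
gene_subsets <- function(classification, tiers = c(1L, 2L),
                         include_fusion_mixed = FALSE) {
  stopifnot(inherits(classification, "gene_classification"))
  g <- classification$genes
  g <- g[g$tier %in% tiers, , drop = FALSE]
  tsg_cats <- "pure_tsg"
  og_cats <- "pure_og"
  if (include_fusion_mixed) {
    tsg_cats <- c(tsg_cats, "tsg_fusion")
    og_cats <- c(og_cats, "og_fusion")
  }
  tsg <- g$gene[g$category %in% tsg_cats]
  list(
    tsg = tsg,
    og = g$gene[g$category %in% og_cats],
    gatekeeper = g$gene[g$category %in% tsg_cats & g$tsg_class == "gatekeeper"],
    caretaker = g$gene[g$category %in% tsg_cats & g$tsg_class == "caretaker"]
  )
}

## internal constructor for the genes x species count container
new_gene_count_table <- function(counts, found, genes, species) {
  counts <- as.matrix(counts)
  found <- as.matrix(found)
  storage.mode(counts) <- "integer"
  stopifnot(identical(dim(counts), dim(found)),
            nrow(counts) == length(genes), ncol(counts) == length(species))
  if (any(counts[found] < 0L)) stop("copy counts must be nonnegative")
  dimnames(counts) <- dimnames(found) <- list(genes, species)
  structure(list(counts = counts, found = found,
                 genes = genes, species = species),
            class = "gene_count_table")
}

#' @export
print.gene_count_table <- function(x, ...) {
  cat("Gene count table:", length(x$genes), "genes x",
      length(x$species), "species;",
      sum(x$found), "found gene-species pairs\n")
  invisible(x)
}

#' Assemble a count table from CAFE-style gene trees
#'
#' For each gene tree, leaf counts are extracted with
#' [extract_cafe_counts()]; `found[g, s]` records whether species `s`
#' appears as a leaf in gene `g`'s tree. A species missing from a tree
#' is missing data, not a zero count.
#'
#' @param gene_trees named list (gene -> `phylo` or Newick string).
#' @param species character vector of species to tabulate (canonicalized).
#' @param pattern count-suffix rule passed to [extract_cafe_counts()].
#' @return a `gene_count_table`.
#' @export
counts_from_gene_trees <- function(gene_trees, species,
                                   pattern = "_([0-9]+)$") {
  species <- unique(canonical_species(species))
  if (length(species) == 0L) stop("species list must be nonempty")
  genes <- names(gene_trees)
  if (length(gene_trees) && is.null(genes))
    stop("gene_trees must be a named list")
  counts <- matrix(0L, length(gene_trees), length(species))
  found <- matrix(FALSE, length(gene_trees), length(species))
  for (i in seq_along(gene_trees)) {
    cc <- extract_cafe_counts(gene_trees[[i]], pattern = pattern)
    hit <- intersect(names(cc), species)
    j <- match(hit, species)
    counts[i, j] <- cc[hit]
    found[i, j] <- TRUE
  }
  new_gene_count_table(counts, found, genes %||% character(0), species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a count table from ortholog records
#'
#' Counts the distinct confident ortholog identifiers per gene-species
#' pair ("homolog approach"). Duplicate records are counted once;
#' `found` is true whenever any record exists for the pair, regardless
#' of confidence, so a pair with only low-confidence records is a
#' found-but-zero cell, distinct from a pair with no records at all.
#'
#' @param records data frame with columns `gene`, `species`,
#'   `ortholog_id`, `confidence` (logical or 0/1).
#' @param species optional species universe; defaults to the species
#'   present in `records`.
#' @return a `gene_count_table`.
#' @export
counts_from_ortholog_records <- function(records, species = NULL) {
  stopifnot(is.data.frame(records),
            all(c("gene", "species", "ortholog_id", "confidence") %in% names(records)))
  records$species <- canonical_species(records$species)
  conf <- as.logical(records$confidence)
  if (anyNA(conf)) stop("confidence must be binary (TRUE/FALSE or 0/1)")
  species <- unique(canonical_species(species %||% records$species))
  if (length(species) == 0L) stop("species list must be nonempty")
  genes <- sort(unique(as.character(records$gene)))
  counts <- matrix(0L, length(genes), length(species))
  found <- matrix(FALSE, length(genes), length(species))
  gi <- match(records$gene, genes)
  si <- match(records$species, species)
  keep <- !is.na(si)
  found[cbind(gi[keep], si[keep])] <- TRUE
  ok <- keep & conf
  if (any(ok)) {
    key <- paste(gi[ok], si[ok], records$ortholog_id[ok], sep = "\r")
    uniq <- !duplicated(key)
    tab <- table(factor(paste(gi[ok][uniq], si[ok][uniq], sep = "\r")))
    ij <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    counts[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- as.integer(tab)
  }
  new_gene_count_table(counts, found, genes, species)
}

#' Normalize copy counts to copies per found gene
#'
#' For each species, the sum of copy counts over the genes of the subset
#' that were found in that species, divided by the number of such found
#' genes -- the mean number of copies per found gene. This compensates
#' for orthologs missing due to incomplete genome assembly: a gene with
#' no ortholog record is excluded from both numerator and denominator,
#' never treated as a zero count.
#'
#' @param table a `gene_count_table`.
#' @param genes gene subset (character); default all genes in the table.
#' @return named numeric vector, species -> normalized count. Species
#'   with no found gene in the subset are omitted with a warning.
#' @export
normalize_counts <- function(table, genes = NULL) {
  stopifnot(inherits(table, "gene_count_table"))
  genes <- genes %||% table$genes
  keep <- table$genes %in% genes
  if (!any(keep)) stop("gene subset is disjoint from the count table")
  counts <- table$counts[keep, , drop = FALSE]
  found <- table$found[keep, , drop = FALSE]
  n_found <- colSums(found)
  total <- colSums(counts * found)
  empty <- n_found == 0
  if (any(empty))
    warning("species with zero found genes omitted: ",
            paste(table$species[empty], collapse = ", "))
  stats::setNames(total[!empty] / n_found[!empty], table$species[!empty])
}

#' TSG/OG ratio
#'
#' Normalized TSG count divided by normalized OG count. Because a
#' whole-genome duplication multiplies both counts, the ratio is
#' invariant to lineage-specific genome doublings, allowing polyploid
#' lineages to be compared with the rest. The ratio is reported as is,
#' without standardization.
#'
#' @param norm_tsg,norm_og named numeric vectors over the same species.
#' @return named numeric vector of ratios.
#' @export
tsg_og_ratio <- function(norm_tsg, norm_og) {
  stopifnot(length(norm_tsg) == length(norm_og))
  if (!is.null(names(norm_tsg)) && !is.null(names(norm_og)) &&
      !identical(names(norm_tsg), names(norm_og)))
    stop("norm_tsg and norm_og must be over the same species, in order")
  bad <- which(!(norm_og > 0))
  if (length(bad))
    stop("TSG/OG ratio undefined (normalized OG count <= 0) for: ",
         paste(names(norm_og)[bad] %||% bad, collapse = ", "))
  norm_tsg / norm_og
}

#' Standardize values to z-scores
#'
#' Centered and scaled with the sample standard deviation (n-1
#' denominator); the output has mean 0 and SD 1.
#'
#' @param values numeric vector with at least two distinct values.
#' @return numeric vector of z-scores, names preserved.
#' @export
zscore <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant vector (SD = 0)")
  (values - mean(values)) / s
}

#' Per-species normalized counts, ratios and z-scores
#'
#' Convenience builder combining [normalize_counts()], [tsg_og_ratio()]
#' and [zscore()] for the four gene subsets. Standardization is over all
#' species surviving ingestion (all species with defined normalized TSG
#' and OG counts), prior to any model-specific subsetting.
#'
#' @param table a `gene_count_table`.
#' @param subsets a [gene_subsets()] result (or any list with elements
#'   `tsg`, `og` and optionally `gatekeeper`, `caretaker`).
#' @return data frame keyed by `species` with columns `norm_tsg`,
#'   `norm_og`, `norm_gatekeeper`, `norm_caretaker` (NA when the subset
#'   is empty), `ratio_tsg_og`, and z-score columns `z_*`.
#' @export
normalized_counts <- function(table, subsets) {
  stopifnot(all(c("tsg", "og") %in% names(subsets)))
  nt <- normalize_counts(table, subsets$tsg)
  no <- normalize_counts(table, subsets$og)
  species <- intersect(names(nt), names(no))
  if (length(species) < 2L)
    stop("fewer than two species with both TSG and OG normalized counts")
  out <- data.frame(species = species,
                    norm_tsg = nt[species], norm_og = no[species],
                    stringsAsFactors = FALSE, row.names = species)
  for (sub in c("gatekeeper", "caretaker")) {
    col <- paste0("norm_", sub)
    out[[col]] <- NA_real_
    gg <- subsets[[sub]]
    if (!is.null(gg) && length(gg) && any(table$genes %in% gg)) {
      v <- normalize_counts(table, gg)
      out[[col]] <- unname(v[match(species, names(v))])
    }
  }
  out$ratio_tsg_og <- tsg_og_ratio(out$norm_tsg, out$norm_og)
  out$z_tsg <- zscore(out$norm_tsg)
  out$z_og <- zscore(out$norm_og)
  out$z_gatekeeper <- if (all(is.finite(out$norm_gatekeeper)))
    zscore(out$norm_gatekeeper) else NA_real_
  out$z_caretaker <- if (all(is.finite(out$norm_caretaker)))
    zscore(out$norm_caretaker) else NA_real_
  out
}

#' Read a COSMIC-census-like CSV
#'
#' Accepts either the package's plain column names (`gene`, `role`,
#' `tier`, `somatic`, `germline`) or COSMIC census export headers
#' ("Gene Symbol", "Role in Cancer", "Tier", "Somatic", "Germline").
#'
#' @param path CSV file path.
#' @return data frame with plain column names.
#' @export
read_cosmic_census <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ren <- c("Gene Symbol" = "gene", "Role in Cancer" = "role",
           "Tier" = "tier", "Somatic" = "somatic", "Germline" = "germline")
  hit <- names(df) %in% names(ren)
  names(df)[hit] <- ren[names(df)[hit]]
  if (!all(c("gene", "role", "tier") %in% names(df)))
    stop("census file must provide gene, role and tier columns")
  df
}

#' Read a gatekeeper/caretaker annotation TSV
#'
#' Two columns: `gene`, `class` ("gatekeeper" or "caretaker").
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_gatekeeper_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "class") %in% names(df)))
    stop("annotation file must have columns 'gene' and 'class'")
  df
}

#' Write / read a gene count table as TSV with a found-mask companion
#'
#' @param table a `gene_count_table`.
#' @param counts_file path for the counts TSV (genes x species).
#' @param found_file path for the logical found-mask TSV.
#' @export
write_count_table <- function(table, counts_file, found_file) {
  stopifnot(inherits(table, "gene_count_table"))
  cc <- table$counts
  cc[!table$found] <- NA_integer_
  utils::write.table(data.frame(gene = table$genes, cc, check.names = FALSE),
                     counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = table$genes, table$found, check.names = FALSE),
                     found_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' @rdname write_count_table
#' @param counts_file,found_file file paths as written by
#'   [write_count_table()].
#' @return a `gene_count_table`.
#' @export
read_count_table <- function(counts_file, found_file) {
  cc <- utils::read.delim(counts_file, check.names = FALSE)
  ff <- utils::read.delim(found_file, check.names = FALSE)
  genes <- as.character(cc$gene)
  stopifnot(identical(genes, as.character(ff$gene)))
  cm <- as.matrix(cc[, -1, drop = FALSE])
  fm <- as.matrix(ff[, -1, drop = FALSE]) == TRUE
  cm[!fm] <- 0L
  new_gene_count_table(cm, fm, genes, colnames(cm))
}
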
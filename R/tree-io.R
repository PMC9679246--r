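#' Canonicalize species names
#'
#' Trait tables, trees and ortholog tables typically come from different
#' sources with inconsistent naming ("Salmo salar", "salmo_salar",
#' "Salmo_Salar"). All ingestion points map names through this function:
#' lowercase, whitespace collapsed to single underscores, surrounding
#' quotes and blanks stripped.
#'
#' @param x character vector of species names.
#' @return character vector of canonical names.
#' @export
#' @examples
#' canonical_species(c("Salmo salar", "DANIO  RERIO"))
canonical_species <- function(x) {
  x <- gsub("^['\"]|['\"]$", "", trimws(as.character(x)))
  tolower(gsub("[[:space:]]+", "_", x))
}

#' Read and validate a rooted Newick tree
#'
#' Parses a single Newick statement into an [ape::read.tree()] `phylo`
#' object and validates it: unique leaf labels after canonicalization,
#' nonnegative branch lengths (missing lengths default to 0). Leaf labels
#' are canonicalized via [canonical_species()].
#'
#' @param text a Newick string terminated by `;`.
#' @return a `phylo` tree with canonical tip labels.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty Newick string")
  semi <- which(strsplit(txt, "")[[1]] == ";")
  if (length(semi) == 0L)
    stop("malformed Newick: missing terminating ';'")
  if (length(semi) > 1L || semi[1] != nchar(txt))
    stop(sprintf("malformed Newick: dangling text after ';' at character offset %d",
                 semi[1]))
  .check_parens(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("malformed Newick: could not be parsed as a tree")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyNA(tree$edge.length))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree$tip.label <- canonical_species(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels after canonicalization: ",
         paste(dup, collapse = ", "))
  tree
}

## balanced-parenthesis scan reporting the first offending character offset
.check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character offset %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' by character offset %d",
                 depth, length(chars)))
  invisible(TRUE)
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param digits number of significant digits for branch lengths.
#' @return a Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-leaf depths equal within a relative tolerance. Required
#' before the delta branch-length transformation, which acts on node
#' depths and is only meaningful on a time-calibrated tree.
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance on the depth spread.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) <= tol * mx
}

#' Root-to-node depths
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric vector of depths indexed by node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0, nrow(tree$edge))
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + el[e]
  }
  depth
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `taxa`: unary internal nodes are
#' collapsed by summing branch lengths, so all pairwise path lengths
#' between retained leaves are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of leaf labels to keep (canonicalized);
#'   must contain at least two names present in the tree.
#' @return the pruned `phylo` tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(canonical_species(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2L)
    stop("at least two taxa must be retained")
  ape::keep.tip(tree, taxa)
}

#' Extract per-species copy counts from a CAFE-style gene tree
#'
#' CAFE exports annotate each leaf with the gene-family copy count for
#' that species. The default dialect appends the count to the species
#' label (`danio_rerio_3`); the suffix rule is a configurable regular
#' expression whose first capture group is the integer count.
#'
#' A species absent from the tree is absent from the returned map, which
#' is distinct from a species present with count 0.
#'
#' @param gene_tree a `phylo` object or a Newick string.
#' @param pattern regular expression matching the count suffix; group 1
#'   must capture the integer count. Default `"_([0-9]+)$"`.
#' @return named integer vector, species -> copy count.
#' @export
#' @examples
#' extract_cafe_counts("(danio_rerio_3:10,salmo_salar_5:10);")
extract_cafe_counts <- function(gene_tree, pattern = "_([0-9]+)$") {
  if (is.character(gene_tree)) gene_tree <- read_newick(gene_tree)
  stopifnot(inherits(gene_tree, "phylo"))
  labs <- gene_tree$tip.label
  m <- regexec(pattern, labs)
  hits <- regmatches(labs, m)
  bad <- labs[vapply(hits, length, 1L) < 2L]
  if (length(bad))
    stop("leaf label(s) lack a parseable count suffix: ",
         paste(bad, collapse = ", "))
  counts <- as.integer(vapply(hits, `[`, "", 2L))
  species <- canonical_species(sub(pattern, "", labs))
  dup <- unique(species[duplicated(species)])
  if (length(dup))
    stop("species appear more than once in the gene tree: ",
         paste(dup, collapse = ", "))
  stats::setNames(counts, species)
}

#' Read a file of gene trees with a sidecar gene map
#'
#' Gene trees are stored one Newick statement per line; a sidecar TSV
#' (columns `line`, `gene`) maps line numbers to gene symbols.
#'
#' @param newick_file path to the Newick-per-line file.
#' @param map_file path to the sidecar TSV.
#' @return named list of `phylo` objects, one per gene.
#' @export
read_gene_trees <- function(newick_file, map_file) {
  lines <- readLines(newick_file)
  lines <- lines[nzchar(trimws(lines))]
  map <- utils::read.delim(map_file, stringsAsFactors = FALSE)
  if (!all(c("line", "gene") %in% names(map)))
    stop("gene map must have columns 'line' and 'gene'")
  if (any(map$line < 1L | map$line > length(lines)))
    stop("gene map refers to lines outside the Newick file")
  trees <- lapply(map$line, function(i) read_newick(lines[i]))
  names(trees) <- map$gene
  trees
}
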
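#' Read a rooted phylogenetic tree from Newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' model needs: every branch carries a nonnegative length and tip labels are
#' unique. Multifurcations are accepted; the pruning recursion handles them
#' natively.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text a Newick string.
#' @return an [ape::phylo] tree.
#' @export
#' @examples
#' tr <- readTree(text = "((s3:1,s4:1):0.5,(s5:1,s6:1):0.5);")
readTree <- function(file = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick input")
  validate_tree(tree)
  tree
}

#' Write a tree to Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param file output path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeTree <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a binary presence/absence profile matrix
#'
#' Reads a delimited table of 0/1 entries with gene ids in the first column
#' and genome ids in the header, or the transpose (`orientation =
#' "genomes_x_genes"`). The delimiter is inferred from the file extension
#' (`.csv` is comma, anything else tab) unless `sep` is given.
#'
#' @param file path to the table.
#' @param orientation `"genes_x_genomes"` (default) or `"genomes_x_genes"`.
#' @param sep field separator override.
#' @return an integer matrix, genes as rows, genomes as columns, entries 0/1.
#' @export
readProfiles <- function(file,
                         orientation = c("genes_x_genomes", "genomes_x_genes"),
                         sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- read.table(file, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty profile table")
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (orientation == "genomes_x_genes") m <- t(m)
  validateProfiles(m)
}

#' Validate a profile matrix
#'
#' Checks that all entries are 0/1 with no missing values and gene ids are
#' unique; returns the matrix with integer storage.
#'
#' @param pm matrix, genes as rows, genomes as columns.
#' @return the validated integer matrix.
#' @export
validateProfiles <- function(pm) {
  if (!is.matrix(pm) || nrow(pm) == 0L || ncol(pm) == 0L)
    stop("profile matrix must be a non-empty matrix")
  if (anyNA(pm)) stop("profile matrix contains missing values")
  if (!all(pm %in% c(0L, 1L)))
    stop("profile entries must be 0 or 1; found: ",
         paste(utils::head(setdiff(unique(as.vector(pm)), 0:1)), collapse = ", "))
  if (!is.null(rownames(pm)) && anyDuplicated(rownames(pm)))
    stop("duplicate gene ids in profile matrix")
  storage.mode(pm) <- "integer"
  pm
}

#' Write a profile matrix
#'
#' @param pm profile matrix (genes x genomes).
#' @param file output path; `.csv` writes comma-separated, otherwise tab.
#' @param sep optional separator override.
#' @export
writeProfiles <- function(pm, file, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  write.table(cbind(gene = rownames(pm), as.data.frame(pm)), file,
              sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Align a profile matrix to a tree
#'
#' Reorders genome columns into the tree's deterministic left-to-right tip
#' order. Genomes absent from the tree are dropped with a warning; tree tips
#' absent from the matrix are an error.
#'
#' @param pm profile matrix (genes x genomes).
#' @param tree an [ape::phylo] tree.
#' @return the reordered profile matrix, columns in tip order.
#' @export
alignToTree <- function(pm, tree) {
  pm <- validateProfiles(pm)
  validate_tree(tree)
  ord <- tip_order(tree)
  if (is.null(colnames(pm)))
    stop("profile matrix must have genome ids as column names")
  miss <- setdiff(ord, colnames(pm))
  if (length(miss))
    stop("tree tips absent from profiles: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(pm), ord)
  if (length(extra))
    warning("dropping ", length(extra), " genome(s) not in the tree: ",
            paste(utils::head(extra, 5), collapse = ", "))
  pm[, ord, drop = FALSE]
}

#' Filter genes by presence frequency
#'
#' Removes genes that are very rare or very common across genomes: a gene
#' with presence fraction `p` is kept iff `min_frac <= p <= max_frac`
#' (strictly-outside genes removed, boundary-equal genes kept). The defaults
#' drop genes present in fewer than 1% or more than 99% of genomes.
#'
#' @param pm profile matrix (genes x genomes).
#' @param min_frac minimum presence fraction (default 0.01).
#' @param max_frac maximum presence fraction (default 0.99).
#' @return the filtered profile matrix (possibly zero rows, with a warning).
#' @export
filterByFrequency <- function(pm, min_frac = 0.01, max_frac = 0.99) {
  pm <- validateProfiles(pm)
  if (!(min_frac >= 0 && min_frac < max_frac && max_frac <= 1))
    stop("require 0 <= min_frac < max_frac <= 1")
  p <- rowMeans(pm)
  keep <- p >= min_frac & p <= max_frac
  if (!any(keep)) warning("frequency filter removed all genes")
  pm[keep, , drop = FALSE]
}
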
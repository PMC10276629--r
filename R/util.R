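# Internal helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Validate a rooted ape tree for use in the model: branch lengths present and
# nonnegative, unique tip labels.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be an ape \"phylo\" object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all edges must carry a length")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  invisible(tree)
}

# Deterministic left-to-right tip order (cladewise traversal, i.e. the order
# tips are written in the Newick string and drawn in a plot). Used wherever
# "consecutive genomes" must be well defined.
tip_order <- function(tree) {
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  idx <- e[e[, 2] <= length(tree$tip.label), 2]
  tree$tip.label[idx]
}

# Postorder edge matrix + lengths for the pruning kernel.
prep_tree <- function(tree) {
  validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, elen = po$edge.length,
       n_tip = length(tree$tip.label),
       n_node = length(tree$tip.label) + tree$Nnode,
       tip.label = tree$tip.label)
}

# Tips descending from each internal node, as a list indexed by node id.
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Deterministic per-task seed derivation from a master seed (counter scheme,
# kept within the 32-bit integer range).
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

# Map profile columns (genomes) onto tree tips, returning the 0-based joint
# state index per tip in tree$tip.label order.
tip_state_index <- function(profiles, tree) {
  labs <- tree$tip.label
  if (is.null(colnames(profiles)))
    stop("profile matrix must have genome ids as column names")
  miss <- setdiff(labs, colnames(profiles))
  if (length(miss))
    stop("tree tips absent from profiles: ", paste(miss, collapse = ", "))
  pm <- profiles[, labs, drop = FALSE]
  n <- nrow(pm)
  pow <- 2^(seq_len(n) - 1L)
  as.integer(colSums(pm * pow))
}
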
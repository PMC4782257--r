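#' Parse and write Newick trees
#'
#' Thin validated wrappers around `ape` tree I/O, so the pipeline's tree
#' handling has a single entry point. Parsing requires branch lengths;
#' writing round-trips topology, labels and branch lengths.
#'
#' @param text a Newick string.
#' @return `parse_newick`: an `ape::phylo` tree; `write_newick`: a Newick
#'   string.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not read tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' @rdname parse_newick
#' @param tree an `ape::phylo` tree.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}

#' Resolve polytomies into zero-length bifurcations
#'
#' Multifurcating nodes are expanded into arbitrary bifurcations joined by
#' zero-length branches, so patristic distances (and hence the phylogenetic
#' covariance) are unchanged. The expansion order is randomized but
#' reproducible from `seed`.
#'
#' @param tree an `ape::phylo` tree.
#' @param seed integer seed controlling the randomized resolution.
#' @return a fully bifurcating `ape::phylo` tree.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  set.seed(as.integer(seed))
  ape::multi2di(tree, random = TRUE)
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds tip depths. Rows and columns are named by tip label.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @return an N x N symmetric positive semi-definite matrix.
#' @export
phylo_covariance <- function(tree) {
  ape::vcv(tree)
}

tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

# floor zero-length branches (from polytomy resolution) for GLS machinery
floor_branches <- function(tree, frac = 1e-8) {
  eps <- frac * tree_depth(tree)
  tree$edge.length[tree$edge.length < eps] <- eps
  tree
}

# reorder a row-named trait matrix to the tree's tip labels; hard error on
# mismatch -- matching is by label, never by position
match_to_tips <- function(tree, traits) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("trait matrix must have species rownames matching tip labels")
  missing_sp <- setdiff(tree$tip.label, rownames(traits))
  if (length(missing_sp))
    stop("traits missing for tips: ", paste(missing_sp, collapse = ", "))
  traits[tree$tip.label, , drop = FALSE]
}

#' Phylogenetic independent contrasts for a trait matrix
#'
#' Felsenstein's contrasts computed column-wise, with the standard
#' branch-length inflation propagated rootward. Rows of the trait matrix are
#' matched to tips by label. The tree must be bifurcating
#' (see [resolve_polytomies()]); zero-length branches are floored at
#' 1e-8 x tree depth to avoid division by zero.
#'
#' @param tree a rooted, bifurcating `ape::phylo` tree.
#' @param traits N x p matrix with species rownames.
#' @return a list with `contrasts` ((N-1) x p matrix, rows named by internal
#'   node id), `node_order` (internal node ids) and `sd_normalizers`
#'   (the square roots of the contrast variances).
#' @export
pic_matrix <- function(tree, traits) {
  if (!ape::is.binary(tree))
    stop("tree has polytomies; resolve them first with resolve_polytomies()")
  traits <- match_to_tips(tree, traits)
  tree <- floor_branches(tree)
  p <- ncol(traits)
  first <- ape::pic(traits[, 1], tree, var.contrasts = TRUE)
  n_int <- nrow(first)
  contrasts <- matrix(NA_real_, n_int, p)
  contrasts[, 1] <- first[, 1]
  if (p > 1) for (j in 2:p)
    contrasts[, j] <- ape::pic(traits[, j], tree)
  node_ids <- as.integer(rownames(first))
  rownames(contrasts) <- rownames(first)
  colnames(contrasts) <- colnames(traits)
  list(contrasts = contrasts, node_order = node_ids,
       sd_normalizers = sqrt(first[, 2]))
}

#' Ancestral state reconstruction under Brownian motion
#'
#' States at internal nodes minimizing the branch-length-weighted sum of
#' squared changes along the tree -- the squared-change-parsimony solution,
#' which equals the maximum-likelihood / generalized-least-squares estimate
#' under Brownian motion. `weighted = FALSE` gives the unweighted
#' (equal-branch) squared-change-parsimony variant by setting all branch
#' lengths to 1 before solving.
#'
#' Implemented by dense GLS: the root state per trait is
#' \eqn{(1' C^{-1} x)/(1' C^{-1} 1)} and every other internal node u is the
#' conditional expectation \eqn{\hat a + c_u' C^{-1} (x - \hat a 1)}, where
#' `c_u` holds shared path lengths between node u and each tip.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @param traits N x p matrix with species rownames.
#' @param weighted use branch-length weighting (the BM-ML form); if `FALSE`
#'   all branch lengths are treated as equal.
#' @return (N-1) x p matrix of internal-node states; rows named by ape node
#'   id (the root is node N+1).
#' @export
ancestral_states <- function(tree, traits, weighted = TRUE) {
  traits <- match_to_tips(tree, traits)
  if (!weighted) tree$edge.length <- rep(1, nrow(tree$edge))
  tree <- floor_branches(tree)
  N <- ape::Ntip(tree)
  n_node <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  # mrca over all (tip, internal) pairs
  M <- ape::mrca(tree, full = TRUE)
  C <- phylo_covariance(tree)
  Ci <- chol2inv(chol(C))
  one <- rep(1, N)
  denom <- sum(Ci)
  a_hat <- colSums(Ci %*% traits) / denom  # (1'C^-1 X)/(1'C^-1 1)
  resid <- sweep(traits, 2, a_hat)
  int_ids <- N + seq_len(n_node)
  # shared path length node u vs tip i = depth of mrca(u, i)
  Cu <- matrix(depths[M[int_ids, seq_len(N)]], n_node, N)
  est <- matrix(rep(a_hat, each = n_node), n_node, ncol(traits)) +
    (Cu %*% Ci) %*% resid
  rownames(est) <- int_ids
  colnames(est) <- colnames(traits)
  est
}
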
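#' Linear map from tip values to standardized independent contrasts
#'
#' Felsenstein's pruning algorithm expresses every standardized contrast
#' as a fixed linear combination of tip values; this function returns that
#' (J-1) x J matrix together with the internal-node ids it corresponds to.
#' Precomputing the map lets thousands of posterior draws be contrasted by
#' a single matrix product.
#'
#' At each internal node with child values x1, x2 on (extended) branches
#' b1, b2 the contrast is (x1 - x2)/sqrt(b1 + b2), the ancestral value is
#' the branch-length-weighted average (x1/b1 + x2/b2)/(1/b1 + 1/b2), and
#' the node's parent branch is extended by b1*b2/(b1 + b2). The sign of
#' each contrast depends on which child is "first"; the rank correlations
#' downstream are not invariant to flipping a single node's sign in only
#' one variable, so the order is fixed deterministically: the child whose
#' smallest descendant tip label sorts first (lexicographically, C
#' collation) supplies the minuend. Applying the same convention to every
#' variable on the same tree makes all contrast sets sign-compatible, and
#' the convention cancels when the tree's newick child order is permuted.
#'
#' @param tree A valid rooted binary `phylo` with positive branch lengths.
#' @return A list with `L` (the contrast matrix, columns named by tip
#'   label), `node_ids` (internal node numbers in `tree`'s postorder) and
#'   `tip_labels`.
#' @export
pic_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  coefs <- matrix(0, ntip + nnode, ntip,
                  dimnames = list(NULL, tr$tip.label))
  coefs[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  blen <- numeric(ntip + nnode)
  blen[tr$edge[, 2]] <- tr$edge.length
  mintip <- character(ntip + nnode)
  mintip[seq_len(ntip)] <- tr$tip.label
  L <- matrix(0, ntip - 1, ntip, dimnames = list(NULL, tr$tip.label))
  node_ids <- integer(ntip - 1)
  # postorder lists all child edges before their parent's own edge
  nodes <- unique(tr$edge[, 1])
  row <- 0L
  for (nd in nodes) {
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    if (length(ch) != 2L) stop("tree is not strictly binary at node ", nd)
    labs <- c(mintip[ch[1]], mintip[ch[2]])
    if (sort(labs, method = "radix")[1] != labs[1]) ch <- rev(ch)
    b1 <- blen[ch[1]]; b2 <- blen[ch[2]]
    row <- row + 1L
    L[row, ] <- (coefs[ch[1], ] - coefs[ch[2], ]) / sqrt(b1 + b2)
    node_ids[row] <- nd
    coefs[nd, ] <- (coefs[ch[1], ] * b2 + coefs[ch[2], ] * b1) / (b1 + b2)
    blen[nd] <- blen[nd] + b1 * b2 / (b1 + b2)
    mintip[nd] <- sort(labs, method = "radix")[1]
  }
  list(L = L, node_ids = node_ids, tip_labels = tr$tip.label)
}

#' Phylogenetically independent contrasts of one variable
#'
#' Standard Felsenstein contrasts, standardized by the square root of the
#' summed (adjusted) branch lengths, with the deterministic sign
#' convention of [pic_matrix()].
#'
#' @param tree A valid rooted binary `phylo`.
#' @param tip_values Named numeric vector covering exactly the tree's tips.
#' @param variable_name Optional label carried on the result.
#' @return A list of class `contrast_set` with `node_ids`, `contrasts`
#'   and `variable_name`.
#' @export
compute_pics <- function(tree, tip_values, variable_name = deparse(substitute(tip_values))) {
  pm <- pic_matrix(tree)
  contrasts_from_matrix(pm, tip_values, variable_name)
}

contrasts_from_matrix <- function(pm, tip_values, variable_name = "x") {
  if (is.null(names(tip_values))) stop("tip_values must be named by tip label")
  miss <- setdiff(pm$tip_labels, names(tip_values))
  if (length(miss)) stop("tip_values missing for tip(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(tip_values), pm$tip_labels)
  if (length(extra)) stop("tip_values given for unknown tip(s): ", paste(extra, collapse = ", "))
  x <- tip_values[pm$tip_labels]
  structure(
    list(node_ids = pm$node_ids,
         contrasts = as.numeric(pm$L %*% x),
         variable_name = variable_name),
    class = "contrast_set"
  )
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation, (C - D)/sqrt((n0 - Tx)(n0 - Ty))
#' with C/D the concordant/discordant pair counts, n0 = n(n-1)/2 and T
#' the within-variable tie-pair counts; identical to the classic tau-a
#' when no ties occur.
#'
#' @param x,y Numeric vectors of equal length >= 2, aligned elementwise.
#' @return Tau in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2) stop("need at least 2 paired values")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite and complete")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("Kendall's tau is undefined when all values of x or y are tied")
  }
  stats::cor(x, y, method = "kendall")
}

#' Kendall correlation between the contrasts of two variables
#'
#' Computes independent contrasts for both variables on the same tree with
#' the same deterministic sign convention, then their tau-b. This is the
#' phylogenetically controlled correlation used throughout the pipeline.
#'
#' @param tree A valid rooted binary `phylo`.
#' @param values_x,values_y Named numeric vectors covering the tips.
#' @return Tau in `[-1, 1]`.
#' @export
tau_on_contrasts <- function(tree, values_x, values_y) {
  pm <- pic_matrix(tree)
  cx <- contrasts_from_matrix(pm, values_x)$contrasts
  cy <- contrasts_from_matrix(pm, values_y)$contrasts
  kendall_tau(cx, cy)
}

#' Export a set of contrasts as a data frame
#'
#' @param ... `contrast_set` objects from the same tree.
#' @return Data frame with columns `node_id`, `variable`, `contrast`.
#' @export
contrasts_as_data_frame <- function(...) {
  sets <- list(...)
  do.call(rbind, lapply(sets, function(cs) {
    data.frame(node_id = cs$node_ids, variable = cs$variable_name,
               contrast = cs$contrasts, stringsAsFactors = FALSE)
  }))
}
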
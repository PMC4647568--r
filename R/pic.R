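#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm on a rooted binary tree. In post-order,
#' a node with child values x1, x2 on working branch lengths v1, v2 yields
#' the raw contrast x1 - x2 with expected variance v1 + v2; the node is
#' assigned the weighted value (x1/v1 + x2/v2)/(1/v1 + 1/v2) and its own
#' branch is lengthened by v1*v2/(v1 + v2). Standardized contrasts are the
#' raw contrasts divided by the square root of their expected variance;
#' under Brownian evolution they are independent with common variance equal
#' to the rate parameter.
#'
#' Zero-length working branches (as produced by polytomy resolution) are
#' replaced by 1e-8 of the tree depth before pruning.
#'
#' @param tree a rooted binary `"phylo"` tree with positive branch lengths.
#' @param traits named numeric vector covering all tips.
#' @return an object of class `"contrast_set"`: a data.frame with one row
#'   per internal node (post-order), columns `node`, `raw`, `variance`,
#'   `contrast` (standardized), and `ntip - 1` rows.
#' @seealso [contrast_regression()]
#' @export
#' @examples
#' tr <- read_newick("(A:1,B:3);")
#' pic_contrasts(tr, c(A = 5, B = 1))  # one contrast: (5-1)/sqrt(4) = 2
pic_contrasts <- function(tree, traits) {
  tree <- validate_tree(tree, polytomies = "error")
  x <- match_traits(tree, traits)
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("need at least 2 tips")
  nnode <- tree$Nnode
  depth <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-8 * max(depth, 1)

  val <- c(x, rep(NA_real_, nnode))
  # working branch length of the edge above each node
  vlen <- rep(NA_real_, ntip + nnode)
  vlen[tree$edge[, 2]] <- pmax(tree$edge.length, eps)

  children <- split(tree$edge[, 2], tree$edge[, 1])
  # explicit post-order over internal nodes (children before parents),
  # independent of ape's internal node numbering convention
  stack <- ntip + 1L
  seen <- integer(0)
  while (length(stack) > 0) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, nd)
    kids <- children[[as.character(nd)]]
    stack <- c(stack, kids[kids > ntip])
  }
  post <- rev(seen)

  out <- data.frame(node = integer(nnode), raw = numeric(nnode),
                    variance = numeric(nnode), contrast = numeric(nnode))
  k <- 0L
  for (nd in post) {
    kids <- children[[as.character(nd)]]
    if (length(kids) != 2) stop("tree is not binary at node ", nd)
    v1 <- vlen[kids[1]]; v2 <- vlen[kids[2]]
    x1 <- val[kids[1]]; x2 <- val[kids[2]]
    k <- k + 1L
    out$node[k] <- nd
    out$raw[k] <- x1 - x2
    out$variance[k] <- v1 + v2
    out$contrast[k] <- (x1 - x2) / sqrt(v1 + v2)
    val[nd] <- (x1 / v1 + x2 / v2) / (1 / v1 + 1 / v2)
    if (nd != ntip + 1L) vlen[nd] <- vlen[nd] + v1 * v2 / (v1 + v2)
  }
  class(out) <- c("contrast_set", "data.frame")
  out
}

#' Through-origin regression of one contrast set on another
#'
#' Independent contrasts have an arbitrary sign (each depends on which
#' sister is subtracted from which), so the regression must pass through the
#' origin and is invariant to joint sign flips of an (x, y) pair. Following
#' convention, the x contrasts are positivized and the paired y contrasts
#' flipped in tandem before fitting. The slope is
#' beta = sum(cx * cy) / sum(cx^2), the residual variance
#' s^2 = (sum(cy^2) - beta * sum(cx * cy)) / (k - 1) with k contrasts, and
#' t = beta / sqrt(s^2 / sum(cx^2)) on k - 1 degrees of freedom, two-sided.
#'
#' @param cx,cy `"contrast_set"` objects from the same tree (same node
#'   order), or bare numeric vectors of standardized contrasts.
#' @return list with `slope`, `t`, `df`, `p`, `k`.
#' @export
contrast_regression <- function(cx, cy) {
  gx <- if (is.data.frame(cx)) cx$contrast else as.numeric(cx)
  gy <- if (is.data.frame(cy)) cy$contrast else as.numeric(cy)
  if (is.data.frame(cx) && is.data.frame(cy) &&
      !identical(cx$node, cy$node)) {
    stop("contrast sets come from different trees or node orders")
  }
  k <- length(gx)
  if (length(gy) != k) stop("contrast sets differ in length")
  if (k < 2) stop("need at least 2 contrasts")
  flip <- sign(gx)
  flip[flip == 0] <- 1
  gx <- gx * flip
  gy <- gy * flip
  sxx <- sum(gx^2)
  if (sxx == 0) stop("all x contrasts are zero: slope undefined")
  sxy <- sum(gx * gy)
  syy <- sum(gy^2)
  beta <- sxy / sxx
  s2 <- max(syy - beta * sxy, 0) / (k - 1)
  tstat <- if (s2 == 0) Inf * sign(beta) else beta / sqrt(s2 / sxx)
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = k - 1)
  list(slope = beta, t = tstat, df = k - 1, p = p, k = k)
}
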
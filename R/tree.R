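#' Read a rooted, branch-length-bearing tree from Newick
#'
#' Parses Newick text (or a file) into an `ape` `"phylo"` tree and validates
#' it for comparative analysis: unique tip labels, a branch length on every
#' non-root edge, and all branch lengths positive. Polytomies are rejected by
#' default; with `polytomies = "resolve"` they are broken into a caterpillar
#' of zero-length branches (warned about), which downstream contrast code
#' replaces by a negligible length.
#'
#' @param source Newick text (containing `;`) or a file path.
#' @param polytomies `"error"` (default) or `"resolve"`.
#' @return a rooted `"phylo"` tree.
#' @seealso [write_newick()], [ape::read.tree()]
#' @export
#' @examples
#' read_newick("(A:1,B:1);")
read_newick <- function(source, polytomies = c("error", "resolve")) {
  polytomies <- match.arg(polytomies)
  tree <- if (grepl(";", source, fixed = TRUE)) {
    ape::read.tree(text = source)
  } else {
    ape::read.tree(source)
  }
  if (is.null(tree)) stop("could not parse Newick input")
  validate_tree(tree, polytomies = polytomies)
}

#' Serialise a tree to Newick text
#'
#' Branch lengths are written with 10 significant digits, so a
#' read/write/read cycle preserves topology and lengths.
#'
#' @param tree a `"phylo"` tree.
#' @return a Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' Validate a tree for comparative analysis
#'
#' @param tree a `"phylo"` tree.
#' @param polytomies `"error"` to reject non-binary trees, `"resolve"` to
#'   break polytomies into zero-length caterpillars with a warning,
#'   `"allow"` to accept them (squared-change parsimony does not require a
#'   binary tree).
#' @return the validated (possibly resolved) tree.
#' @export
validate_tree <- function(tree, polytomies = c("error", "resolve", "allow")) {
  polytomies <- match.arg(polytomies)
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      any(is.na(tree$edge.length))) {
    stop("every non-root node must carry a branch length")
  }
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (polytomies == "error") {
      stop("tree contains polytomies; set polytomies = \"resolve\" to break them")
    }
    if (polytomies == "resolve") {
      warning("resolving polytomies into zero-length caterpillar branches")
      tree <- ape::multi2di(tree, random = FALSE)
      tree$edge.length[tree$edge.length <= 0] <- 0
    }
  }
  tree
}

#' Match a trait vector to the tips of a tree
#'
#' @param tree a `"phylo"` tree.
#' @param traits named numeric vector; names must be exactly the tip labels.
#' @return numeric vector ordered as `tree$tip.label`.
#' @export
match_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by tip label")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing) > 0) {
    stop("missing trait values for tips: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(traits), tree$tip.label)
  if (length(extra) > 0) {
    stop("trait names not on the tree: ", paste(extra, collapse = ", "))
  }
  v <- as.numeric(traits[tree$tip.label])
  if (any(!is.finite(v))) stop("trait values must be finite")
  stats::setNames(v, tree$tip.label)
}

#' Read a two-column trait table
#'
#' CSV dialect `tip,value` with a header row.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Path to a packaged example file
#'
#' Lists or returns files shipped under `inst/extdata`: the published
#' per-species score distributions and transformation tallies, the
#' central/fringe zone counts, and a synthetic approximation of the
#' time-calibrated Triturus species tree.
#'
#' @param file file name; `NULL` lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
vertvar_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "vertvar")))
  }
  path <- system.file("extdata", file, package = "vertvar")
  if (path == "") stop("no packaged file '", file, "'")
  path
}

#' The Triturus species tree used in examples
#'
#' An eight-tip rooted ultrametric tree with the published topology
#' (((marmoratus, pygmaeus), ((ivanbureschi, karelinii), ((carnifex,
#' macedonicus), (cristatus, dobrogicus))))). Node ages in million years are
#' a synthetic approximation: the source phylogeny is time-calibrated but its
#' branch lengths are not printed, so results that depend on exact lengths
#' (permutation p-values, contrast regressions) will differ from analyses on
#' the true calibrated tree. Override with your own Newick via
#' [read_newick()].
#'
#' @return a `"phylo"` tree with 8 tips.
#' @export
triturus_tree <- function() {
  read_newick(vertvar_example("triturus_tree_synthetic.nwk"))
}
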
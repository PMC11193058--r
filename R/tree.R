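#' Build a taxonomic tree from lineage strings
#'
#' Each observed feature supplies an ordered vector of rank names (for example
#' phylum down to genus). Identical lineage prefixes merge into shared internal
#' nodes; internal nodes are keyed by the full prefix joined with ";" so that
#' identical genus names under different families remain distinct. Unary
#' chains (internal nodes with a single child) are collapsed, since they would
#' duplicate a column of the ancestry matrix and create perfectly collinear
#' aggregated features.
#'
#' @param lineages named list (or named character vector of ";"-separated
#'   strings) mapping feature id to its lineage, root-most rank first.
#' @return an \code{ape} \code{phylo} object with labelled internal nodes.
#' @export
treeFromLineages <- function(lineages) {
  if (is.character(lineages)) lineages <- as.list(lineages)
  lineages <- lapply(lineages, function(x) {
    unlist(strsplit(as.character(x), ";", fixed = TRUE))
  })
  featureIds <- names(lineages)
  if (is.null(featureIds) || anyDuplicated(featureIds)) {
    stop("lineages must be uniquely named by feature id")
  }
  if (any(vapply(lineages, length, 1L) == 0)) {
    stop("every feature must have a non-empty lineage")
  }
  p <- length(lineages)
  prefixKeys <- unique(unlist(lapply(lineages, function(ln) {
    vapply(seq_along(ln), function(k) paste(ln[seq_len(k)], collapse = ";"), "")
  })))
  # order internal nodes by depth then key: parents always precede children
  depth <- lengths(strsplit(prefixKeys, ";", fixed = TRUE))
  prefixKeys <- prefixKeys[order(depth, prefixKeys)]
  if (any(prefixKeys %in% featureIds)) {
    stop("internal node keys clash with feature ids: ",
         paste(intersect(prefixKeys, featureIds), collapse = ", "))
  }
  nInternal <- length(prefixKeys) + 1L # plus root
  nodeNum <- c(stats::setNames(seq_len(p), featureIds),
               root = p + 1L,
               stats::setNames(p + 1L + seq_along(prefixKeys), prefixKeys))
  parentKey <- function(key) {
    parts <- strsplit(key, ";", fixed = TRUE)[[1]]
    if (length(parts) == 1) "root"
    else paste(parts[-length(parts)], collapse = ";")
  }
  edges <- rbind(
    cbind(nodeNum[vapply(prefixKeys, parentKey, "")], nodeNum[prefixKeys]),
    cbind(nodeNum[vapply(lineages, paste, "", collapse = ";")],
          seq_len(p))
  )
  tr <- structure(list(
    edge = unname(edges),
    tip.label = featureIds,
    node.label = c("root", prefixKeys),
    Nnode = nInternal
  ), class = "phylo", order = "cladewise")
  .tidyTree(tr)
}

#' Read a taxonomic tree from a Newick file
#'
#' Branch lengths are ignored; unnamed internal nodes receive deterministic
#' labels; unary chains are collapsed (see [treeFromLineages()]).
#'
#' @param path path to a Newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
treeFromNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names in ", path, ": ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr$edge.length <- NULL
  .tidyTree(tr)
}

# collapse unary chains, root the tree conceptually at node ntip+1, and make
# sure every internal node carries a unique label
.tidyTree <- function(tr) {
  tr <- ape::collapse.singles(tr)
  if (is.null(tr$node.label)) {
    tr$node.label <- rep("", tr$Nnode)
  }
  blank <- is.na(tr$node.label) | tr$node.label == ""
  tr$node.label[blank] <- paste0("node", which(blank))
  if (anyDuplicated(c(tr$tip.label, tr$node.label))) {
    tr$node.label <- make.unique(c(tr$tip.label, tr$node.label),
                                 sep = "_")[-seq_along(tr$tip.label)]
  }
  tr
}

#' Build the binary ancestry matrix of a taxonomic tree
#'
#' Returns the \code{p x (|T|-1)} incidence matrix over all nodes except the
#' root: \code{a[j, u] = 1} when leaf \code{j} is the node (leaf columns form
#' an identity block) or descends from internal node \code{u}. Column order is
#' leaves first, in \code{leafOrder}, then internal nodes in depth-first
#' post-order (children visited in the tree's edge order), which is stable
#' across runs.
#'
#' @param tree an \code{ape} \code{phylo} with uniquely labelled nodes.
#' @param leafOrder permutation of the tree's tip labels giving the row (and
#'   leaf-column) order; defaults to the tree's tip order.
#' @return an \linkS4class{AncestryMatrix}.
#' @export
buildAncestryMatrix <- function(tree, leafOrder = tree$tip.label) {
  tree <- .tidyTree(tree)
  p <- length(tree$tip.label)
  if (length(leafOrder) != p || !setequal(leafOrder, tree$tip.label)) {
    stop("leafOrder must be a permutation of the tree's leaf labels")
  }
  root <- p + 1L
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(p + tree$Nnode)))
  # iterative DFS from the root recording internal nodes in post-order and
  # accumulating descendant tip sets
  tipsUnder <- vector("list", p + tree$Nnode)
  for (i in seq_len(p)) tipsUnder[[i]] <- i
  postIntern <- integer(0)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      kids <- children[[node]]
      for (k in rev(kids)) {
        if (k > p) stack[[length(stack) + 1L]] <- list(node = k, stage = 1L)
      }
    } else {
      kids <- children[[node]]
      tipsUnder[[node]] <- sort(unlist(tipsUnder[kids]))
      if (node != root) postIntern <- c(postIntern, node)
    }
  }
  internLabels <- tree$node.label[postIntern - p]
  leafIdx <- match(leafOrder, tree$tip.label)
  a <- matrix(0, p, p + length(postIntern),
              dimnames = list(leafOrder, c(leafOrder, internLabels)))
  a[cbind(seq_len(p), seq_len(p))] <- 1
  for (j in seq_along(postIntern)) {
    rows <- match(tree$tip.label[tipsUnder[[postIntern[j]]]], leafOrder)
    a[rows, p + j] <- 1
  }
  new("AncestryMatrix", a = a, leafIds = leafOrder,
      nodeIds = colnames(a),
      isLeaf = c(rep(TRUE, p), rep(FALSE, length(postIntern))))
}

#' Tree-aggregated design matrix
#'
#' Computes \code{Xtilde = X A}: the observed leaf columns followed by, for
#' every internal node, the sum of its descendant leaf columns.
#'
#' @param x samples-by-leaves matrix (log relative abundances) whose column
#'   order matches the ancestry matrix's leaf order.
#' @param A an \linkS4class{AncestryMatrix}.
#' @return samples-by-nodes matrix.
#' @export
aggregateFeatures <- function(x, A) {
  stopifnot(is(A, "AncestryMatrix"))
  if (!identical(colnames(x), A@leafIds)) {
    stop("column order of x must equal the leaf order of the ancestry matrix")
  }
  x %*% A@a
}

#' Zero-sum constraint vector on the aggregated scale
#'
#' \code{c = t(A) 1_p}: the entry for node \code{u} counts the observed leaves
#' descending from it. A left vector \code{u} with \code{t(c) u = 0} yields a
#' leaf-level coefficient vector \code{A u} that sums to zero, the
#' identifiability constraint required by compositional predictors.
#'
#' @param A an \linkS4class{AncestryMatrix}.
#' @return named numeric vector of length \code{ncol(A)}.
#' @export
constraintVector <- function(A) {
  stopifnot(is(A, "AncestryMatrix"))
  colSums(A@a)
}
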
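#' @importFrom methods new validObject is slot setClass setGeneric setMethod setValidity show
NULL

#' Ancestry (leaf-by-node incidence) matrix of a taxonomic tree
#'
#' Binary matrix with one row per observed leaf feature and one column per
#' tree node other than the root (leaves included). Entry \code{a[j, u] = 1}
#' when leaf \code{j} descends from node \code{u} (or \code{j == u} for leaf
#' columns). Multiplying a sample-by-leaf design by this matrix appends
#' tree-aggregated features: the column for an internal node is the sum of the
#' columns of its descendant leaves.
#'
#' Column order is deterministic: leaf columns first, in the leaf order used to
#' build the matrix, then internal nodes in depth-first post-order.
#'
#' @slot a binary numeric matrix, \code{p x (|T|-1)}, with dimnames.
#' @slot leafIds character vector of the p leaf (observed feature) identifiers.
#' @slot nodeIds character vector of all non-root node identifiers (columns).
#' @slot isLeaf logical vector marking which columns are leaves.
#' @export
setClass("AncestryMatrix",
  representation(
    a = "matrix",
    leafIds = "character",
    nodeIds = "character",
    isLeaf = "logical"
  )
)

setValidity("AncestryMatrix", function(object) {
  msg <- character()
  a <- object@a
  if (!is.numeric(a)) msg <- c(msg, "'a' must be numeric")
  if (any(a != 0 & a != 1)) msg <- c(msg, "'a' must be binary")
  if (nrow(a) != length(object@leafIds)) {
    msg <- c(msg, "nrow(a) must equal length(leafIds)")
  }
  if (ncol(a) != length(object@nodeIds)) {
    msg <- c(msg, "ncol(a) must equal length(nodeIds)")
  }
  if (length(object@isLeaf) != ncol(a)) {
    msg <- c(msg, "isLeaf must have one entry per column")
  }
  if (anyDuplicated(object@leafIds)) msg <- c(msg, "duplicate leaf ids")
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "duplicate node ids")
  if (length(msg) == 0 && any(object@isLeaf)) {
    leafBlock <- a[, object@isLeaf, drop = FALSE]
    if (nrow(leafBlock) != ncol(leafBlock) ||
        !all(leafBlock[cbind(
          match(colnames(leafBlock), object@leafIds),
          seq_len(ncol(leafBlock))
        )] == 1) ||
        !all(colSums(leafBlock) == 1)) {
      msg <- c(msg, "leaf columns must form a permuted identity block")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted tree-aggregated factor regression model
#'
#' Result of the sequential sparse unit-rank extraction. The coefficient
#' matrix on the aggregated design is \code{Gamma = U diag(d) t(V)}; the
#' leaf-level coefficient matrix is \code{C = A Gamma} and every column of C
#' sums to zero (compositional identifiability).
#'
#' @slot beta numeric matrix (m x q) of unpenalized covariate effects.
#' @slot d numeric vector of estimated singular values (length = rank).
#' @slot U numeric matrix ((|T|-1) x rank) of sparse left vectors, unit norm.
#' @slot V numeric matrix (q x rank) of sparse right vectors, unit norm.
#' @slot Chat numeric matrix (p x q), leaf-level coefficients A Gamma;
#'   zero-row matrix placeholder until assembled with an ancestry matrix.
#' @slot cvec numeric constraint vector c = t(A) 1_p used in the fit.
#' @slot diagnostics list: per-component chosen lambda, criterion paths,
#'   convergence flags, per-step beta estimates, dropped columns.
#' @export
setClass("TreeFarFit",
  representation(
    beta = "matrix",
    d = "numeric",
    U = "matrix",
    V = "matrix",
    Chat = "matrix",
    cvec = "numeric",
    diagnostics = "list"
  )
)

setValidity("TreeFarFit", function(object) {
  msg <- character()
  r <- length(object@d)
  if (ncol(object@U) != r || ncol(object@V) != r) {
    msg <- c(msg, "U and V must have one column per singular value")
  }
  if (any(object@d < 0)) msg <- c(msg, "singular values must be non-negative")
  if (r > 0 && length(object@cvec) == nrow(object@U)) {
    viol <- max(abs(crossprod(object@cvec, object@U)))
    if (viol > 1e-6) {
      msg <- c(msg, sprintf("constraint violation |c'u| = %.2e", viol))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted linear-constrained reduced-rank regression (dense baseline)
#'
#' Reduced-rank regression on the aggregated design under the zero-sum
#' constraint, with no sparsity penalty: the rank-r truncation of the
#' ridge-stabilized least-squares solution inside the constraint null space.
#'
#' @slot beta numeric matrix (m x q) of covariate effects.
#' @slot Gamma numeric matrix ((|T|-1) x q) of rank <= rank.
#' @slot d,U,V SVD factors of Gamma (dense, for support-recovery scoring).
#' @slot Chat leaf-level coefficients A Gamma once assembled.
#' @slot cvec constraint vector used.
#' @slot rank integer rank requested.
#' @export
setClass("CrrrFit",
  representation(
    beta = "matrix",
    Gamma = "matrix",
    d = "numeric",
    U = "matrix",
    V = "matrix",
    Chat = "matrix",
    cvec = "numeric",
    rank = "integer"
  )
)

setValidity("CrrrFit", function(object) {
  msg <- character()
  if (length(object@cvec) == nrow(object@Gamma) && length(object@Gamma) > 0) {
    viol <- max(abs(crossprod(object@cvec, object@Gamma)))
    scale <- max(1, max(abs(object@Gamma)))
    if (viol / scale > 1e-6) {
      msg <- c(msg, sprintf("constraint violation |c'Gamma| = %.2e", viol))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Specification of one synthetic benchmark experiment
#'
#' Captures the full recipe for one simulated microbiome-metabolome dataset:
#' dimensions, taxonomy shape, which feature sets carry signal, the low-rank
#' coefficient structure, and the signal-to-noise ratio.
#'
#' Settings: \code{"a"} high-variation leaves carry signal, \code{"b"} rare
#' (low-prevalence) leaves, \code{"c"} any leaves, \code{"d"} internal
#' (aggregated) nodes only.
#'
#' @slot n number of samples.
#' @slot p number of leaf features.
#' @slot q number of response variables.
#' @slot m number of covariate columns (first is the intercept).
#' @slot setting one of "a", "b", "c", "d".
#' @slot rank true rank of the coefficient matrix.
#' @slot d true singular values, strictly positive and decreasing.
#' @slot signalFraction fraction of features carrying signal (union of
#'   u-supports across components).
#' @slot vFraction fraction of responses in each component's v-support.
#' @slot snr signal-to-noise ratio (weakest-layer convention).
#' @slot treeDepth maximum depth of the simulated taxonomy.
#' @slot zeroInflA,zeroInflB Beta shape parameters of per-feature prevalence.
#' @slot mu0,sigma0 mean and sd of per-feature lognormal location.
#' @slot sigma1 per-sample lognormal scale.
#' @slot meanDepth mean sequencing depth.
#' @slot seed integer seed making the dataset reproducible.
#' @export
setClass("SimulationDesign",
  representation(
    n = "integer",
    p = "integer",
    q = "integer",
    m = "integer",
    setting = "character",
    rank = "integer",
    d = "numeric",
    signalFraction = "numeric",
    vFraction = "numeric",
    snr = "numeric",
    treeDepth = "integer",
    zeroInflA = "numeric",
    zeroInflB = "numeric",
    mu0 = "numeric",
    sigma0 = "numeric",
    sigma1 = "numeric",
    meanDepth = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (object@n < 2) msg <- c(msg, "n must be >= 2")
  if (object@p < 4) msg <- c(msg, "p must be >= 4")
  if (!(object@setting %in% c("a", "b", "c", "d"))) {
    msg <- c(msg, "setting must be one of 'a','b','c','d'")
  }
  if (object@rank < 1) msg <- c(msg, "rank must be >= 1")
  if (length(object@d) != object@rank) {
    msg <- c(msg, "d must have 'rank' entries")
  }
  if (any(object@d <= 0) || is.unsorted(rev(object@d))) {
    msg <- c(msg, "d must be strictly positive and non-increasing")
  }
  if (object@signalFraction <= 0 || object@signalFraction >= 1) {
    msg <- c(msg, "signalFraction must be in (0,1)")
  }
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (object@m < 1) msg <- c(msg, "m must be >= 1 (intercept)")
  if (length(msg)) msg else TRUE
})
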
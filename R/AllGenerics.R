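#' Accessors for fitted factor-regression objects
#'
#' \code{coefC} returns the leaf-level coefficient matrix \code{C = A Gamma};
#' \code{coefGamma} the node-level coefficient matrix; \code{singularValues},
#' \code{leftVectors}, \code{rightVectors} the SVD factors;
#' \code{estimatedRank} the number of extracted components;
#' \code{constraintVec} the zero-sum constraint vector used in the fit.
#'
#' @param object a \linkS4class{TreeFarFit} or \linkS4class{CrrrFit}.
#' @return the requested component.
#' @name fit-accessors
#' @aliases coefC coefGamma singularValues leftVectors rightVectors
#'   estimatedRank constraintVec
NULL

#' @rdname fit-accessors
#' @export
setGeneric("coefC", function(object) standardGeneric("coefC"))

#' @rdname fit-accessors
#' @export
setGeneric("coefGamma", function(object) standardGeneric("coefGamma"))

#' @rdname fit-accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname fit-accessors
#' @export
setGeneric("leftVectors", function(object) standardGeneric("leftVectors"))

#' @rdname fit-accessors
#' @export
setGeneric("rightVectors", function(object) standardGeneric("rightVectors"))

#' @rdname fit-accessors
#' @export
setGeneric("estimatedRank", function(object) standardGeneric("estimatedRank"))

#' @rdname fit-accessors
#' @export
setGeneric("constraintVec", function(object) standardGeneric("constraintVec"))

#' Assemble leaf-level coefficients from a fitted model
#'
#' Maps node-level coefficients back to the observed leaf features through the
#' ancestry matrix: \code{C = A Gamma}. Every column of the result sums to
#' zero because each fitted left vector satisfies the constraint
#' \code{t(c) u = 0} with \code{c = t(A) 1_p}.
#'
#' @param object fitted model (\linkS4class{TreeFarFit} or
#'   \linkS4class{CrrrFit}).
#' @param A an \linkS4class{AncestryMatrix}.
#' @return the fitted object with its \code{Chat} slot populated.
#' @export
setGeneric("assembleC", function(object, A) standardGeneric("assembleC"))

#' @rdname AncestryMatrix-class
#' @param object an \code{AncestryMatrix}.
#' @export
setGeneric("leafIds", function(object) standardGeneric("leafIds"))

#' @rdname AncestryMatrix-class
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname AncestryMatrix-class
#' @export
setGeneric("ancestry", function(object) standardGeneric("ancestry"))

setMethod("ancestry", "AncestryMatrix", function(object) object@a)
setMethod("leafIds", "AncestryMatrix", function(object) object@leafIds)
setMethod("nodeIds", "AncestryMatrix", function(object) object@nodeIds)

setMethod("coefC", "TreeFarFit", function(object) object@Chat)
setMethod("coefC", "CrrrFit", function(object) object@Chat)
setMethod("coefGamma", "TreeFarFit", function(object) {
  if (length(object@d) == 0) {
    matrix(0, nrow(object@U), nrow(object@V))
  } else {
    object@U %*% (object@d * t(object@V))
  }
})
setMethod("coefGamma", "CrrrFit", function(object) object@Gamma)
setMethod("singularValues", "TreeFarFit", function(object) object@d)
setMethod("singularValues", "CrrrFit", function(object) object@d)
setMethod("leftVectors", "TreeFarFit", function(object) object@U)
setMethod("leftVectors", "CrrrFit", function(object) object@U)
setMethod("rightVectors", "TreeFarFit", function(object) object@V)
setMethod("rightVectors", "CrrrFit", function(object) object@V)
setMethod("estimatedRank", "TreeFarFit", function(object) length(object@d))
setMethod("estimatedRank", "CrrrFit", function(object) object@rank)
setMethod("constraintVec", "TreeFarFit", function(object) object@cvec)
setMethod("constraintVec", "CrrrFit", function(object) object@cvec)

setMethod("show", "AncestryMatrix", function(object) {
  cat("AncestryMatrix:", length(object@leafIds), "leaves,",
      length(object@nodeIds), "non-root nodes (",
      sum(!object@isLeaf), "internal )\n")
})

setMethod("show", "TreeFarFit", function(object) {
  r <- length(object@d)
  cat("TreeFarFit: rank", r, "\n")
  if (r > 0) {
    cat("  singular values:", paste(signif(object@d, 4), collapse = ", "), "\n")
    cat("  nonzero per u:", paste(colSums(object@U != 0), collapse = ", "),
        " | per v:", paste(colSums(object@V != 0), collapse = ", "), "\n")
  }
  cat("  beta:", nrow(object@beta), "x", ncol(object@beta), "\n")
  if (nrow(object@Chat) > 0) {
    cat("  C:", nrow(object@Chat), "x", ncol(object@Chat),
        "(max |col sum| =", format(max(abs(colSums(object@Chat))), digits = 3),
        ")\n")
  }
})

setMethod("show", "CrrrFit", function(object) {
  cat("CrrrFit: rank", object@rank, "(dense constrained reduced-rank fit)\n")
})

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: setting (%s), n=%d, p=%d, q=%d, m=%d, rank=%d, snr=%g, seed=%d\n",
    object@setting, object@n, object@p, object@q, object@m, object@rank,
    object@snr, object@seed))
})
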
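#' @name mammofuse-accessors
#' @title Accessors for mammofuse S4 containers
#' @description Small accessor generics for the package's S4 classes.
#' @param object an S4 object from this package.
NULL

#' @rdname mammofuse-accessors
#' @export
setGeneric("images", function(object) standardGeneric("images"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("imageLabels", function(object) standardGeneric("imageLabels"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("lesionMasks", function(object) standardGeneric("lesionMasks"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("nImages", function(object) standardGeneric("nImages"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("selectionMask", function(object) standardGeneric("selectionMask"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("selectionHistory",
           function(object) standardGeneric("selectionHistory"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("confusionMatrix",
           function(object) standardGeneric("confusionMatrix"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("fusedValues", function(object) standardGeneric("fusedValues"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("entropyWeights",
           function(object) standardGeneric("entropyWeights"))

#' @rdname mammofuse-accessors
#' @export
setGeneric("canonicalCorrelation",
           function(object) standardGeneric("canonicalCorrelation"))

#' Count learnable parameters of a network
#'
#' Sums every learnable scalar: convolution kernels and biases, batch-norm
#' scale and shift (running statistics are not learnable), and dense weights
#' and biases.
#'
#' @param object a [Network-class] (or [NetworkSpec-class]).
#' @return integer-valued numeric scalar.
#' @export
setGeneric("countParameters",
           function(object) standardGeneric("countParameters"))

# -- accessor methods ---------------------------------------------------------

#' @rdname mammofuse-accessors
#' @export
setMethod("images", "MammoImageSet", function(object) object@images)

#' @rdname mammofuse-accessors
#' @export
setMethod("imageLabels", "MammoImageSet", function(object) object@labels)

#' @rdname mammofuse-accessors
#' @export
setMethod("lesionMasks", "MammoImageSet", function(object) object@lesionMasks)

#' @rdname mammofuse-accessors
#' @export
setMethod("nImages", "MammoImageSet", function(object) length(object@images))

#' @rdname mammofuse-accessors
#' @export
setMethod("selectionMask", "SelectionResult", function(object) object@mask)

#' @rdname mammofuse-accessors
#' @export
setMethod("selectionHistory", "SelectionResult",
          function(object) object@history)

#' @rdname mammofuse-accessors
#' @export
setMethod("confusionMatrix", "MetricsReport",
          function(object) object@confusion)

#' @rdname mammofuse-accessors
#' @export
setMethod("metricValues", "MetricsReport", function(object) object@metrics)

#' @rdname mammofuse-accessors
#' @export
setMethod("fusedValues", "FusedFeatures", function(object) object@values)

#' @rdname mammofuse-accessors
#' @export
setMethod("entropyWeights", "FusedFeatures", function(object) object@weights)

#' @rdname mammofuse-accessors
#' @export
setMethod("canonicalCorrelation", "KccaSolution", function(object) object@rho)

#' @rdname mammofuse-accessors
#' @export
setMethod("canonicalCorrelation", "FusedFeatures",
          function(object) object@kcca@rho)

# -- show methods -------------------------------------------------------------

setMethod("show", "MammoImageSet", function(object) {
  d <- if (nImages(object)) dim(object@images[[1L]]) else c(NA, NA, NA)
  cat(sprintf("MammoImageSet: %d images (%s), %dx%dx%d\n",
              nImages(object),
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels, 2L)), collapse = ", "),
              d[1], d[2], d[3]))
  if (!is.na(object@seed)) cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "Network", function(object) {
  cat(sprintf("Network '%s' (input %s): %s parameters, %s\n",
              object@spec@name,
              paste(object@spec@inputShape, collapse = "x"),
              format(countParameters(object), big.mark = ","),
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "KccaSolution", function(object) {
  cat(sprintf("KccaSolution: rho = %.4f (N = %d, reg = %g)\n",
              object@rho, length(object@xi), object@reg))
})

setMethod("show", "FusedFeatures", function(object) {
  cat(sprintf("FusedFeatures: %d x %d (rho = %.4f)\n",
              nrow(object@values), ncol(object@values), object@kcca@rho))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d/%d columns, cost = %.4f, CV accuracy = %.3f\n",
    sum(object@mask), length(object@mask), object@cost, object@accuracy))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (rows = truth)\n")
  print(object@confusion)
  print(round(object@metrics, 2))
})

setMethod("show", "TTestResult", function(object) {
  cat(sprintf(
    "Paired t: mean |diff| = %.3f, sd = %.3f, t = %.3f (dof = %d)\n",
    object@mean, object@sd, object@t, object@dof))
  cat(sprintf("  interval at p = %.2f: (%.3f, %.3f) -> t %s\n",
              object@pLevel, object@interval[1], object@interval[2],
              if (object@inside) "inside" else "outside"))
})
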
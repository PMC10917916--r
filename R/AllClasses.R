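#' Labeled mammogram image collection
#'
#' Container for a set of grayscale or RGB images with per-image class labels
#' in \{benign, malignant\}, optional lesion masks marking inserted blobs, and
#' the generator seed/parameter provenance. Images are `H x W x C` arrays with
#' intensities in `[0, 1]`; all images in a set share one geometry.
#'
#' @slot images list of `H x W x C` numeric arrays, values in `[0, 1]`.
#' @slot labels factor with levels `benign`, `malignant`, one per image.
#' @slot lesionMasks list of `H x W` logical matrices (or `NULL` entries).
#' @slot seed integer seed the generator was called with (`NA` for data read
#'   from disk).
#' @slot params named list of generator parameters.
#' @exportClass MammoImageSet
setClass("MammoImageSet",
  representation(images = "list", labels = "factor", lesionMasks = "list",
                 seed = "integer", params = "list"))

setValidity("MammoImageSet", function(object) {
  if (length(object@images) != length(object@labels))
    return("number of images and labels differ")
  if (!identical(levels(object@labels), c("benign", "malignant")))
    return("labels must be a factor with levels benign, malignant")
  dims <- unique(lapply(object@images, dim))
  if (length(dims) > 1L)
    return("all images must share the same H x W x C geometry")
  if (length(dims) == 1L && length(dims[[1L]]) != 3L)
    return("images must be H x W x C arrays")
  if (length(object@lesionMasks) &&
      length(object@lesionMasks) != length(object@images))
    return("lesionMasks must be empty or one per image")
  TRUE
})

#' Declarative network architecture description
#'
#' A `NetworkSpec` names an architecture (`three_block`, `four_block`, or a
#' custom identifier), records the expected input geometry and holds the
#' layer graph as a nested list of layer/branch descriptors produced by the
#' internal graph constructors.
#'
#' @slot name character scalar.
#' @slot inputShape integer vector `c(H, W, C)`.
#' @slot graph nested list describing the layer graph.
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(name = "character", inputShape = "integer", graph = "list"))

#' Instantiated trainable network
#'
#' A `Network` binds a [NetworkSpec-class] to concrete parameter arrays
#' (convolution kernels, batch-norm scale/shift and running statistics, dense
#' weights) initialized deterministically from a seed.
#'
#' @slot spec the [NetworkSpec-class] this network realizes.
#' @slot params nested list of parameter arrays, mirroring the spec graph.
#' @slot seed integer initialization seed.
#' @slot trained logical, `TRUE` after [trainNetwork()].
#' @slot history list; training diagnostics (per-epoch loss, hyperparameters).
#' @exportClass Network
setClass("Network",
  representation(spec = "NetworkSpec", params = "list", seed = "integer",
                 trained = "logical", history = "list"))

#' Kernel CCA solution
#'
#' Leading canonical pair of the regularized kernel CCA generalized
#' eigenproblem: dual coefficient vectors `xi`, `eta` (length N) with the
#' normalization `xi' Ku Ku xi = eta' Kv Kv eta = 1`, and the first canonical
#' correlation `rho`, clipped into `[0, 1]`.
#'
#' @slot xi,eta numeric dual coefficient vectors.
#' @slot rho first canonical correlation.
#' @slot reg ridge parameter used.
#' @exportClass KccaSolution
setClass("KccaSolution",
  representation(xi = "numeric", eta = "numeric", rho = "numeric",
                 reg = "numeric"))

#' Fused feature matrix with entropy weights
#'
#' Result of kernel-CCA + entropy fusion: the horizontally concatenated,
#' entropy-weighted feature matrix (`N x (p1 + p2)`), the per-column weights,
#' column provenance, and the kernel-CCA diagnostic solution.
#'
#' @slot values numeric matrix `N x (p1 + p2)`.
#' @slot weights numeric vector of normalized entropy weights, one per column.
#' @slot provenance data.frame with columns `source` and `column`.
#' @slot kcca the [KccaSolution-class] fusion-quality diagnostic.
#' @slot sigma Gaussian kernel bandwidths used for the two views.
#' @exportClass FusedFeatures
setClass("FusedFeatures",
  representation(values = "matrix", weights = "numeric",
                 provenance = "data.frame", kcca = "KccaSolution",
                 sigma = "numeric"))

setValidity("FusedFeatures", function(object) {
  if (ncol(object@values) != length(object@weights))
    return("one weight per fused column required")
  if (nrow(object@provenance) != ncol(object@values))
    return("provenance must have one row per fused column")
  if (any(!is.finite(object@values))) return("fused values must be finite")
  TRUE
})

#' Wrapper feature-selection result
#'
#' Best mask found by the quantum GNDO selector together with the cost that
#' produced it, the cross-validated accuracy of the wrapped classifier on the
#' selected columns, and the best-cost trajectory.
#'
#' @slot mask logical vector over feature columns; at least one `TRUE`.
#' @slot cost numeric scalar, the selection cost (lower is better).
#' @slot accuracy cross-validation accuracy (fraction in `[0, 1]`).
#' @slot history numeric vector of best cost per iteration (nonincreasing).
#' @slot fitnessRatio numeric vector, per-iteration `|f(best)/mean f|`
#'   diagnostic.
#' @slot seed integer seed.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(mask = "logical", cost = "numeric", accuracy = "numeric",
                 history = "numeric", fitnessRatio = "numeric",
                 seed = "integer"))

setValidity("SelectionResult", function(object) {
  if (!any(object@mask)) return("at least one column must be selected")
  if (length(object@history) > 1L &&
      any(diff(object@history) > 1e-12))
    return("best-cost history must be nonincreasing")
  TRUE
})

#' Classification metrics report
#'
#' A 2x2 confusion matrix (rows = truth, columns = prediction, in label order
#' benign, malignant) and the derived performance measures. Accuracy,
#' sensitivity, precision, F1, FNR, G-measure, MCC and kappa are on the
#' percent scale; AUC is in `[0, 1]`.
#'
#' @slot confusion 2x2 integer matrix.
#' @slot metrics named numeric vector (accuracy, sensitivity, precision, f1,
#'   fnr, g_measure, mcc, kappa, auc).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(confusion = "matrix", metrics = "numeric"))

setValidity("MetricsReport", function(object) {
  if (!all(dim(object@confusion) == c(2L, 2L)))
    return("confusion must be 2 x 2")
  if (any(object@confusion < 0)) return("confusion entries must be >= 0")
  TRUE
})

#' Paired Student's t analysis result
#'
#' @slot diffs absolute per-experiment accuracy differences.
#' @slot mean,sd mean and sample standard deviation of the differences.
#' @slot t t statistic `sqrt(N) * mean / sd`.
#' @slot dof degrees of freedom `N - 1`.
#' @slot interval two-sided critical interval at the requested level.
#' @slot pLevel significance level used for the interval.
#' @slot inside logical, whether `t` falls inside the interval.
#' @slot degenerate logical, `TRUE` when all differences are zero.
#' @exportClass TTestResult
setClass("TTestResult",
  representation(diffs = "numeric", mean = "numeric", sd = "numeric",
                 t = "numeric", dof = "numeric", interval = "numeric",
                 pLevel = "numeric", inside = "logical",
                 degenerate = "logical"))
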
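#' @include AllClasses.R
NULL

#' Accessors for fitted network objects
#'
#' `kdFinal()` returns the fitted dissociation constants, `kdTrajectory()`
#' the full per-step matrix, `lossTrajectory()` the per-step loss,
#' `actMatrix()`/`repMatrix()` the derivative-factor matrices
#' (regulator x target) and `fixedMask()` the clamping mask.
#'
#' @param object a [TRNFit-class].
#' @return the corresponding slot value.
#' @name TRNFit-accessors
NULL

#' @rdname TRNFit-accessors
#' @export
setGeneric("kdFinal", function(object) standardGeneric("kdFinal"))
#' @rdname TRNFit-accessors
#' @export
setGeneric("kdTrajectory", function(object) standardGeneric("kdTrajectory"))
#' @rdname TRNFit-accessors
#' @export
setGeneric("lossTrajectory",
           function(object) standardGeneric("lossTrajectory"))
#' @rdname TRNFit-accessors
#' @export
setGeneric("actMatrix", function(object) standardGeneric("actMatrix"))
#' @rdname TRNFit-accessors
#' @export
setGeneric("repMatrix", function(object) standardGeneric("repMatrix"))
#' @rdname TRNFit-accessors
#' @export
setGeneric("fixedMask", function(object) standardGeneric("fixedMask"))

#' @rdname TRNFit-accessors
setMethod("kdFinal", "TRNFit", function(object) object@kdFinal)
#' @rdname TRNFit-accessors
setMethod("kdTrajectory", "TRNFit", function(object) object@kdTrajectory)
#' @rdname TRNFit-accessors
setMethod("lossTrajectory", "TRNFit",
          function(object) object@lossTrajectory)
#' @rdname TRNFit-accessors
setMethod("actMatrix", "TRNFit", function(object) object@AMatrix)
#' @rdname TRNFit-accessors
setMethod("repMatrix", "TRNFit", function(object) object@RMatrix)
#' @rdname TRNFit-accessors
setMethod("fixedMask", "TRNFit", function(object) object@fixedMask)

#' Accessors for network models and region annotations
#'
#' @param object a [TRNModel-class] or [RegionAnnotation-class].
#' @return the corresponding slot value.
#' @name container-accessors
NULL

#' @rdname container-accessors
#' @export
setGeneric("roster", function(object) standardGeneric("roster"))
#' @rdname container-accessors
setMethod("roster", "TRNModel", function(object) object@roster)

#' @rdname container-accessors
#' @export
setGeneric("promoterSites",
           function(object) standardGeneric("promoterSites"))
#' @rdname container-accessors
setMethod("promoterSites", "TRNModel",
          function(object) object@promoterSites)

#' @rdname container-accessors
#' @export
setGeneric("geneBodySites",
           function(object) standardGeneric("geneBodySites"))
#' @rdname container-accessors
setMethod("geneBodySites", "TRNModel",
          function(object) object@geneBodySites)

#' @rdname container-accessors
#' @export
setGeneric("modelParamsOf", function(object) standardGeneric("modelParamsOf"))
#' @rdname container-accessors
setMethod("modelParamsOf", "TRNModel", function(object) object@params)

#' @rdname container-accessors
#' @export
setGeneric("genePromoters",
           function(object) standardGeneric("genePromoters"))
#' @rdname container-accessors
setMethod("genePromoters", "RegionAnnotation",
          function(object) object@promoters)

#' @rdname container-accessors
#' @export
setGeneric("geneBodies", function(object) standardGeneric("geneBodies"))
#' @rdname container-accessors
setMethod("geneBodies", "RegionAnnotation",
          function(object) object@geneBodies)

#' @rdname container-accessors
#' @export
setGeneric("excludedGenes",
           function(object) standardGeneric("excludedGenes"))
#' @rdname container-accessors
setMethod("excludedGenes", "RegionAnnotation",
          function(object) object@excluded)

#' Identify core factors of a fit
#'
#' Core factors are those whose dissociation constant moved during
#' optimisation: `|log10(kdFinal / kdInit)| > tolerance`, clamped factors
#' excluded. The result is sorted by magnitude of change, descending.
#'
#' @param fit a [TRNFit-class].
#' @param tolerance threshold on `|log10(kdFinal/kdInit)|` (default 0.5,
#'   about a 3.2-fold change).
#' @return data.frame with columns `tf_id`, `kd_init`, `kd_final`,
#'   `log10_change`.
#' @export
setGeneric("coreTFs",
           function(fit, tolerance = 0.5) standardGeneric("coreTFs"))
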
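# Generics and accessors for the S4 classes.

#' Number of learnable terms in a model
#' @param object a [UNetModel-class].
#' @return integer total of all learnable array lengths.
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' @rdname nParams
#' @export
setMethod("nParams", "UNetModel", function(object) {
  sum(vapply(unlist(object@params, recursive = FALSE),
             function(x) length(x), numeric(1)))
})

#' Kernel bank accessors
#'
#' `bankKernels()` returns the list of rotated templates, `bankAngles()` the
#' orientation angles in radians.
#'
#' @param object a [KernelBank-class].
#' @return list of matrices, or numeric vector of angles.
#' @export
setGeneric("bankKernels", function(object) standardGeneric("bankKernels"))

#' @rdname bankKernels
#' @export
setMethod("bankKernels", "KernelBank", function(object) object@kernels)

#' @rdname bankKernels
#' @export
setGeneric("bankAngles", function(object) standardGeneric("bankAngles"))

#' @rdname bankKernels
#' @export
setMethod("bankAngles", "KernelBank", function(object) object@angles)

#' Phantom accessors
#'
#' Accessors for the rendered image, the exact vessel ground truth, and the
#' field-of-view mask of a [Phantom-class].
#'
#' @param object a `Phantom`.
#' @return H x W x 3 array, or a logical matrix.
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))

#' @rdname phantomImage
#' @export
setMethod("phantomImage", "Phantom", function(object) object@image)

#' @rdname phantomImage
#' @export
setGeneric("phantomTruth", function(object) standardGeneric("phantomTruth"))

#' @rdname phantomImage
#' @export
setMethod("phantomTruth", "Phantom", function(object) object@gt)

#' @rdname phantomImage
#' @export
setGeneric("phantomFov", function(object) standardGeneric("phantomFov"))

#' @rdname phantomImage
#' @export
setMethod("phantomFov", "Phantom", function(object) object@fov)

#' Model specification accessor
#' @param object a [UNetModel-class].
#' @return the `unetSpec()` list the model was built from.
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))

#' @rdname modelSpec
#' @export
setMethod("modelSpec", "UNetModel", function(object) object@spec)
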
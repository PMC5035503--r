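#' @import methods
#' @importFrom stats cor pchisq rbeta rbinom rpois runif setNames var cmdscale dist
#' @importFrom utils read.table write.table head tail
NULL

#' Accessor generics
#'
#' Small family of accessors used across the package's S4 classes.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return `dosages` returns the SNP-by-animal integer dosage matrix (0/1/2,
#'   `NA` for missing); `markerMap` the per-SNP map as a `data.frame`;
#'   `animalIds` and `snpIds` character vectors of identifiers; `panelSnps`
#'   the ordered SNP ids of a panel; `relMatrix` the genomic relationship
#'   matrix; `imputedMask` the logical SNP-by-animal matrix flagging entries
#'   that were filled (as opposed to observed).
#'
#' @name accessors
#' @aliases dosages markerMap animalIds snpIds panelSnps relMatrix imputedMask
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("markerMap", function(x, ...) standardGeneric("markerMap"))

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x, ...) standardGeneric("animalIds"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x, ...) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("panelSnps", function(x, ...) standardGeneric("panelSnps"))

#' @rdname accessors
#' @export
setGeneric("relMatrix", function(x, ...) standardGeneric("relMatrix"))

#' @rdname accessors
#' @export
setGeneric("imputedMask", function(x, ...) standardGeneric("imputedMask"))
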
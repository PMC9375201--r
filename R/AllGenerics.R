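#' Accessors for MetacellPartition objects
#'
#' \code{membership} returns the 1-based metacell id of every cell;
#' \code{mcSizes} the number of cells per metacell; \code{nMetacells} the
#' number of metacells; \code{gammaLevel} the realised graining level
#' (cells per metacell).
#'
#' @param x a \code{\linkS4class{MetacellPartition}} (or a
#'   \code{\linkS4class{MetacellProfile}} for \code{mcSizes} /
#'   \code{nMetacells}).
#' @return \code{membership}: integer vector; \code{mcSizes}: integer or
#'   numeric vector; \code{nMetacells}: integer; \code{gammaLevel}: numeric.
#' @name partition-accessors
NULL

#' @rdname partition-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname partition-accessors
#' @export
setGeneric("mcSizes", function(x) standardGeneric("mcSizes"))

#' @rdname partition-accessors
#' @export
setGeneric("nMetacells", function(x) standardGeneric("nMetacells"))

#' @rdname partition-accessors
#' @export
setGeneric("gammaLevel", function(x) standardGeneric("gammaLevel"))

#' @rdname partition-accessors
#' @export
setMethod("membership", "MetacellPartition", function(x) x@membership)

#' @rdname partition-accessors
#' @export
setMethod("mcSizes", "MetacellPartition",
          function(x) tabulate(x@membership, max(x@membership)))

#' @rdname partition-accessors
#' @export
setMethod("mcSizes", "MetacellProfile", function(x) x$size)

#' @rdname partition-accessors
#' @export
setMethod("nMetacells", "MetacellPartition", function(x) max(x@membership))

#' @rdname partition-accessors
#' @export
setMethod("nMetacells", "MetacellProfile", function(x) ncol(x))

#' @rdname partition-accessors
#' @export
setMethod("gammaLevel", "MetacellPartition", function(x) x@gamma)

#' Cut a metacell dendrogram at a graining level
#'
#' @param tree a \code{\linkS4class{MetacellDendrogram}}.
#' @param ... arguments passed to methods: exactly one of \code{gamma}
#'   (target graining level, >= 1) or \code{nMetacells} (exact number of
#'   metacells).
#' @return a \code{\linkS4class{MetacellPartition}}.
#' @export
setGeneric("cutToMetacells",
           function(tree, ...) standardGeneric("cutToMetacells"))
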
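#' @include AllClasses.R
NULL

#' Accessors for GenomeRecord and PlastomePartition
#'
#' @param x a [GenomeRecord-class] or [PlastomePartition-class]
#' @return the corresponding slot value (see individual accessors)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setMethod("genomeLength", "GenomeRecord", function(x) length(x@seq))
#' @rdname accessors
#' @export
setMethod("genomeLength", "PlastomePartition", function(x) x@genomeLength)

#' @rdname accessors
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname accessors
#' @export
setMethod("genomeFeatures", "GenomeRecord", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @rdname accessors
#' @export
setMethod("isCircularGenome", "GenomeRecord", function(x) x@circular)

#' @rdname accessors
#' @export
setGeneric("organismName", function(x) standardGeneric("organismName"))
#' @rdname accessors
#' @export
setMethod("organismName", "GenomeRecord", function(x) x@organism)

#' @rdname accessors
#' @export
setGeneric("lscInterval", function(x) standardGeneric("lscInterval"))
#' @rdname accessors
#' @export
setMethod("lscInterval", "PlastomePartition", function(x) x@lsc)
#' @rdname accessors
#' @export
setGeneric("irbInterval", function(x) standardGeneric("irbInterval"))
#' @rdname accessors
#' @export
setMethod("irbInterval", "PlastomePartition", function(x) x@irb)
#' @rdname accessors
#' @export
setGeneric("sscInterval", function(x) standardGeneric("sscInterval"))
#' @rdname accessors
#' @export
setMethod("sscInterval", "PlastomePartition", function(x) x@ssc)
#' @rdname accessors
#' @export
setGeneric("iraInterval", function(x) standardGeneric("iraInterval"))
#' @rdname accessors
#' @export
setMethod("iraInterval", "PlastomePartition", function(x) x@ira)

#' @rdname accessors
#' @export
setGeneric("lscLength", function(x) standardGeneric("lscLength"))
#' @rdname accessors
#' @export
setMethod("lscLength", "PlastomePartition", function(x) diff(x@lsc))
#' @rdname accessors
#' @export
setGeneric("sscLength", function(x) standardGeneric("sscLength"))
#' @rdname accessors
#' @export
setMethod("sscLength", "PlastomePartition", function(x) diff(x@ssc))
#' @rdname accessors
#' @export
setGeneric("irLength", function(x) standardGeneric("irLength"))
#' @rdname accessors
#' @export
setMethod("irLength", "PlastomePartition", function(x) diff(x@irb))

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s'%s: %s bp, %s, %d features\n",
              object@id,
              if (nzchar(object@organism))
                paste0(" (", object@organism, ")") else "",
              format(length(object@seq), big.mark = ","),
              if (object@circular) "circular" else "linear",
              nrow(object@features)))
  kinds <- table(object@features$kind)
  if (length(kinds))
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds),
                    collapse = ", "), "\n", sep = "")
})

setMethod("show", "PlastomePartition", function(object) {
  cat(sprintf(
    "PlastomePartition: %s bp = LSC %s + IRb %s + SSC %s + IRa %s\n",
    format(object@genomeLength, big.mark = ","),
    format(diff(object@lsc), big.mark = ","),
    format(diff(object@irb), big.mark = ","),
    format(diff(object@ssc), big.mark = ","),
    format(diff(object@ira), big.mark = ",")))
})
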
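#' @rdname CircSet-class
#' @param x,object A `CircSet` (or other package class as documented).
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))

#' @rdname CircSet-class
#' @export
setGeneric("circStrands", function(x) standardGeneric("circStrands"))

#' @rdname CircSet-class
#' @export
setGeneric("circChroms", function(x) standardGeneric("circChroms"))

#' @rdname CircSet-class
#' @export
setGeneric("exonBlocks", function(x) standardGeneric("exonBlocks"))

#' @rdname CircSet-class
#' @export
setGeneric("circSequences", function(x) standardGeneric("circSequences"))

#' @rdname CircSet-class
#' @param value Replacement value.
#' @export
setGeneric("circSequences<-",
  function(x, value) standardGeneric("circSequences<-"))

#' @rdname CircSet-class
#' @export
setGeneric("circLengths", function(x) standardGeneric("circLengths"))

#' @rdname JunctionRefDB-class
#' @param x A `JunctionRefDB`.
#' @export
setGeneric("refTable", function(x) standardGeneric("refTable"))

#' @rdname JunctionRefDB-class
#' @export
setGeneric("junctionFlank", function(x) standardGeneric("junctionFlank"))

#' @rdname CorfSet-class
#' @param x A `CorfSet`.
#' @export
setGeneric("corfTable", function(x) standardGeneric("corfTable"))

#' @rdname CodingModel-class
#' @param x A `CodingModel`.
#' @export
setGeneric("testAccuracy", function(x) standardGeneric("testAccuracy"))
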
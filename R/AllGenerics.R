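#' @rdname ZFCohort-class
#' @param x a \code{ZFCohort}.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname ZFCohort-class
#' @param value replacement \code{DataFrame}.
#' @export
setGeneric("proteins<-", function(x, value) standardGeneric("proteins<-"))

#' @rdname ZFCohort-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname ZFCohort-class
#' @export
setGeneric("domains<-", function(x, value) standardGeneric("domains<-"))

#' @rdname ZFCohort-class
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname ZFCohort-class
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))
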
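#' @export
setGeneric("columnBarcodes", function(x) standardGeneric("columnBarcodes"))
#' @export
setGeneric("rowBarcodes", function(x) standardGeneric("rowBarcodes"))
#' @export
setGeneric("fwdPrimer", function(x) standardGeneric("fwdPrimer"))
#' @export
setGeneric("revPrimer", function(x) standardGeneric("revPrimer"))
#' @export
setGeneric("referenceAmplicon", function(x) standardGeneric("referenceAmplicon"))
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))
#' @export
setGeneric("flankSize", function(x) standardGeneric("flankSize"))
#' @export
setGeneric("enumerateWells", function(layout) standardGeneric("enumerateWells"))
#' @export
setGeneric("countPrimers", function(layout) standardGeneric("countPrimers"))
#' @export
setGeneric("expectedAmpliconLength", function(layout) standardGeneric("expectedAmpliconLength"))
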
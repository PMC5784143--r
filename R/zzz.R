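#' @importFrom methods new is setGeneric setMethod validObject
#' @importFrom stats dist sd rnorm runif rpois approx
#' @importFrom utils read.csv write.csv write.table packageVersion
#' @keywords internal
"_PACKAGE"
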
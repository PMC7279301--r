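#' @importFrom graphics abline legend lines par plot
#' @importFrom stats approx dnorm optimize rnorm rpois setNames
#' @importFrom utils head tail read.csv read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL
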
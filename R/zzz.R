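#' @importFrom data.table := .N .SD data.table
#' @importFrom stats median quantile setNames
NULL

# data.table syntax is used throughout the package internals
.datatable.aware <- TRUE
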
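# data.table is used for pileup aggregation; the flag below enables
# data.table-aware [ dispatch inside this package.
#' @importFrom data.table rbindlist setorderv :=
#' @importFrom stats median rnorm rpois runif setNames phyper pbinom
#' @importFrom utils head
NULL

.datatable.aware <- TRUE
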
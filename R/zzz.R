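#' @importFrom data.table data.table as.data.table rbindlist setorder dcast
#'   copy uniqueN := .N .SD
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("key", "serial", "intensity", "sigma", "mean_i",
                         "fac", "half", "nser", "s", "n", "m", "half1",
                         "half2", "node_id", "."))
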
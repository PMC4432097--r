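# Classed conditions used across the package. Every user-facing failure mode
# carries a stable class so callers (and the CLI) can react without string
# matching.

st_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "st_error")))
}

st_parse_error    <- function(msg) st_stop(msg, "st_parse_error")
st_schema_error   <- function(msg) st_stop(msg, "st_schema_error")
st_value_error    <- function(msg) st_stop(msg, "st_value_error")
st_conflict_error <- function(msg) st_stop(msg, "st_conflict_error")
st_notfound_error <- function(msg) st_stop(msg, "st_notfound_error")
st_contract_error <- function(msg) st_stop(msg, "st_contract_error")
st_layout_error   <- function(msg) st_stop(msg, "st_layout_error")
st_dialect_error  <- function(msg) st_stop(msg, "st_dialect_error")
st_geometry_error <- function(msg) st_stop(msg, "st_geometry_error")
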
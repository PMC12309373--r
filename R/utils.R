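# Internal helpers: typed error conditions and deterministic ordering.

abort_input <- function(message, ...) {
  rlang::abort(message, class = "fishnet_input_error", ...)
}

abort_consistency <- function(message, ...) {
  rlang::abort(message, class = c("fishnet_consistency_error", "fishnet_input_error"), ...)
}

abort_domain <- function(message, ...) {
  rlang::abort(message, class = "fishnet_domain_error", ...)
}

abort_convergence <- function(message, ...) {
  rlang::abort(message, class = "fishnet_convergence_error", ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = c("fishnet_config_error", "fishnet_input_error"), ...)
}

# Locale-independent sort so outputs are byte-identical across machines.
sort_c <- function(x) sort(x, method = "radix")

# Order cluster ids like c2 < c10 (shorter numeric suffix first, then radix).
order_ids <- function(ids) order(nchar(ids), ids, method = "radix")

collapse_genes <- function(x) paste(sort_c(x), collapse = ";")
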
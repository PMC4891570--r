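# Internal helpers shared across modules.

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent lexicographic sort for identifiers.
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

stop_if_not_matrix_obj <- function(x, class, arg) {
  if (!inherits(x, class)) {
    stop("`", arg, "` must be a <", class, "> object", call. = FALSE)
  }
}
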
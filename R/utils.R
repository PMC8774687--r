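# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic fingerprint of a character vector, used to stamp bin grids and
# configurations. Polynomial rolling hash mod (2^31 - 1); collisions are
# irrelevant here (the hash only guards against accidental grid mismatches).
fc_hash <- function(x) {
  s <- utf8ToInt(paste(as.character(x), collapse = "\x1f"))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive a 32-bit sub-seed from a master seed and a stream label, so that
# independent stages consume independent but reproducible RNG streams.
fc_subseed <- function(seed, label) {
  s <- utf8ToInt(paste0(label))
  h <- as.numeric(seed) %% 2147483647
  for (b in s) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

fc_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[fragcnv] ", ...)
}

fc_stop <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
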
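#' @keywords internal
"_PACKAGE"

# Affine counter map into [1, 2^31 - 2]; keeps every derived seed a valid
# 32-bit integer so replicate k of grid point i is reproducible in isolation.
substream_seed <- function(master, i = 0L, k = 0L) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + as.double(i) * 1048583 + as.double(k) * 7919
  as.integer(s %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x < 1
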
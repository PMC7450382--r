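#' @importFrom rlang abort warn %||% .data
#' @importFrom stats kruskal.test wilcox.test cor.test sd rnorm rlnorm rpois runif
NULL

# error helper: all package conditions carry a "figcopy_error" class plus a
# specific subclass so callers can branch on the failure kind
stop_figcopy <- function(msg, class, ...) {
  abort(msg, class = c(class, "figcopy_error"), ...)
}

# 32-bit FNV-1a over a string, reduced to a valid R RNG seed (< 2^31).
# Used to derive independent per-session seeds from (master_seed, group, index)
# so cohort generation is reproducible and order-independent.
fnv1a_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\r")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor only touches the low byte (b < 256); done in doubles to stay 32-bit
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so intermediates stay below 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# quantized cell index on a half-open grid [origin, origin + n*cell):
# index 1 covers [origin, origin+cell). Coordinates are snapped at 1e-6 cell
# units first so values a few ulp below a boundary land with the boundary.
cell_index <- function(v, origin, cell, n = NULL) {
  i <- floor(round((v - origin) / cell, 6)) + 1L
  if (!is.null(n)) i[i == n + 1L] <- n  # closed top edge on the last cell
  as.integer(i)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
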
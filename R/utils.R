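# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(deg) deg * pi / 180

#' @keywords internal
#' @noRd
player_key_of <- function(player_id, season) paste(player_id, season, sep = "|")

# Deterministic per-unit seed substream derived from a master seed.
# Kept strictly below 2^31 - 1 so set.seed() accepts it everywhere.
substream_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
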
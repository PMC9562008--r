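# internal helpers shared across modules

#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 31-ary polynomial string hash modulo 2^31-1; stable across sessions and
# platforms (R's own hash of strings is not part of the API)
#' @keywords internal
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# per-spot RNG stream: root xor hash(id), kept inside 32-bit signed range so
# adding or removing a spot never perturbs another spot's draws
#' @keywords internal
derive_seed <- function(root_seed, id) {
  h <- stable_hash(as.character(id))
  s <- bitwXor(as.integer(root_seed) %% 2147483647L, h)
  if (s < 0L) s <- -s
  s
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0
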
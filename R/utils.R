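# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

# Phred+33 quality string <-> integer vector
decode_quals <- function(q) as.integer(charToRaw(q)) - 33L
encode_quals <- function(q) rawToChar(as.raw(as.integer(q) + 33L))

# derive a per-stage seed from a root seed; keeps the result a valid
# 32-bit integer whatever the root is
stage_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * offset) %% 2147483647)
}

# two group labels in order of first appearance; first label is "group A"
group_levels <- function(group) {
  lev <- unique(as.character(group))
  if (length(lev) != 2L)
    stopf("expected exactly 2 group labels, got %d (%s)",
          length(lev), paste(lev, collapse = ", "))
  lev
}
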
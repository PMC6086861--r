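#' @keywords internal
"_PACKAGE"

# round half away from zero; base round() rounds half to even, which would make
# edge counts at a density depend on the parity of the half-integer
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a stage/outcome seed from a master seed; kept below 2^31
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset) %% 2147483647L)
}

# run code with a local RNG state so library calls don't disturb the caller
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
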
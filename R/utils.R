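#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every source of randomness in the package
# draws from a named substream of one master seed, so that independent stages
# (splits, init, dropout, noise) are reproducible in isolation.
sub_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L) + 1L
}

# Evaluate expr under a local RNG state; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "0101" -> "01:01"; resolution inferred from nchar
allele_name_from_digits <- function(digits) {
  n <- nchar(digits)
  stopifnot(n %in% c(2L, 4L, 6L))
  paste(substring(digits, seq(1, n, 2), seq(2, n, 2)), collapse = ":")
}

allele_digits_from_name <- function(name) gsub(":", "", name, fixed = TRUE)

# prefix relation between resolutions: "01" is parent of "01:01"
allele_is_prefix <- function(parent, child) {
  startsWith(paste0(child, ":"), paste0(parent, ":"))
}

allele_resolution <- function(name) {
  2L * (nchar(gsub("[^:]", "", name)) + 1L)
}
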
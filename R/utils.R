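# internal helpers shared across modules

# split a structure string into a character vector of single states
ssChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# derive a child seed from a master seed; stays well below 2^31
childSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) %% 1009L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @importFrom withr with_seed
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
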
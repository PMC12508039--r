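# Seed hygiene: evaluate an expression under a local RNG state so that
# seeded package functions never disturb the caller's random stream.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-module child seed from a root seed. Keeps every derived
# seed inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + as.numeric(stream)) %% 2147483647
}

# Format numbers with 17 significant digits for reproducible CSV output.
fmt17 <- function(x) {
  if (is.double(x)) formatC(x, digits = 17, format = "g") else as.character(x)
}

# Write a data frame as CSV with full-precision numeric columns.
write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
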
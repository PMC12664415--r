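# Shared fixture builders; everything is generated in code.

# Noise-free pseudo-second-order curve.
pso_curve <- function(cs, k, times = seq(10, 80, 10), temperature = 50,
                      method = "UAE", replicate = 1L) {
  extraction_curve(times, pso_predict(cs, k, times), temperature,
                   method, replicate)
}

# Long-format CSV on disk; returns the path.
write_fixture_csv <- function(df, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Independent OLS oracle via explicit normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
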
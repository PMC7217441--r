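# shared fixtures and independent oracles for the test suite

singapore_model <- function() {
  competition_model(c(0.35, 0.29, 0.36), alpha = 1.00, beta = 0.76,
                    names = c("English", "Dialect", "Mandarin"))
}

singapore_x0 <- function() {
  x <- c(0.018, 0.975, 0.001)
  setNames(x / sum(x), c("English", "Dialect", "Mandarin"))
}

# independently coded classical two-language Abrams-Strogatz flow:
# dx1/dt = x2 s1 x1^alpha - x1 s2 x2^alpha (does not depend on the
# beta/aversion split, only on the combined exponent alpha)
as_two_language_oracle <- function(x1, s1, alpha) {
  x2 <- 1 - x1
  s2 <- 1 - s1
  x2 * s1 * x1^alpha - x1 * s2 * x2^alpha
}

random_simplex <- function(n) {
  v <- rexp(n)
  v / sum(v)
}
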
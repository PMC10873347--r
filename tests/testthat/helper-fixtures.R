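# Shared fixtures, built in code.

# A small screen at modest depth for pipeline-level tests.
small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fm <- build_fitness_map("empirical", seed = 1)
      d <- screen_design(depth = 5e5)
      cache <<- list(fitness = fm, design = d,
                     sim = simulate_screen(fm, d, seed = 11))
    }
    cache
  }
})

# Toy two-variant fitness map over the full design space: every variant
# neutral except the two named ones.
toy_fitness <- function(w = c(ASGV = 1, ATGV = 1), base = 1) {
  fm <- build_fitness_map("uniform")
  fm$w_glu[] <- base
  fm$w_gal[] <- base
  fm$w_glu[match(names(w), fm$variant)] <- w
  fm$w_gal[match(names(w), fm$variant)] <- w
  fm
}

# Direct summation oracle for binomial tails, independent of pbinom.
sum_binom_upper <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(i) dbinom(i, n, p), numeric(1)))
}
sum_binom_lower <- function(k, n, p) {
  sum(vapply(0:k, function(i) dbinom(i, n, p), numeric(1)))
}
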
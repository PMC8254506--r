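# Shared fixture builders; all fixtures are generated in code.

# Brute-force oracle for composition enumeration: plain triple loop applying
# the two attachment constraints, independent of the package's enumerator.
oracle_enumerate <- function(max_hex, max_dhex, max_mal) {
  out <- list()
  for (h in 0:max_hex) for (d in 0:max_dhex) for (m in 0:max_mal) {
    if (d >= 1 && h < 1) next
    if (m > h) next
    out[[length(out) + 1]] <- c(h, d, m)
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("n_hex", "n_dhex", "n_mal")
  df[order(df$n_hex, df$n_dhex, df$n_mal), ]
}

# Independent element masses (a second published monoisotopic table, lower
# precision) for cross-checking the packaged one.
oracle_mass <- function(counts) {
  tab <- c(C = 12, H = 1.007825, O = 15.994915, N = 14.003074,
           Na = 22.989770, F = 18.998403, P = 30.973762)
  sum(tab[names(counts)] * counts)
}

# A tiny deterministic peak list: three scans, known peaks.
toy_peak_list <- function() {
  peak_list(data.frame(
    rt = c(10, 10, 20, 30),
    mz = c(271.2420, 500.0, 271.2415, 653.3507),
    intensity = c(100, 50, 80, 40)
  ), sample_id = "toy", group = "control")
}

# Dense Gaussian EIC trace with known closed-form area A * sigma * sqrt(2*pi).
gaussian_trace <- function(A = 1000, mu = 100, sigma = 5, step = 0.2) {
  rt <- seq(mu - 8 * sigma, mu + 8 * sigma, by = step)
  data.frame(rt = rt, intensity = A * exp(-(rt - mu)^2 / (2 * sigma^2)))
}

# Random valid composition under given bounds (rejection-free construction).
random_composition <- function(max_hex = 4, max_dhex = 3, max_mal = 4) {
  h <- sample(0:max_hex, 1)
  d <- if (h >= 1) sample(0:max_dhex, 1) else 0L
  m <- sample(0:min(h, max_mal), 1)
  data.frame(n_hex = h, n_dhex = d, n_mal = m)
}
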
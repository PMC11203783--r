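# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# Fine-grid quadrature of stimulus x illuminant x sensitivity via pracma,
# with everything re-interpolated at `step` nm.
oracle_quantum_catch <- function(spectra, stim, bg, illum_fun, receptors_fun,
                                 step = 0.1) {
  wl <- seq(min(spectra$wavelength_nm), max(spectra$wavelength_nm), by = step)
  interp <- function(col) approx(spectra$wavelength_nm, spectra[[col]], wl)$y
  d <- illum_fun(wl)
  sapply(c("uv", "blue", "green"), function(r) {
    s <- receptors_fun(wl)[[r]]
    pracma::trapz(wl, interp(stim) * s * d) /
      pracma::trapz(wl, interp(bg) * s * d)
  })
}

# Mann-Whitney via pairwise comparison counting and complete labelling
# enumeration (the implementation uses rank sums instead).
oracle_mann_whitney <- function(x, y) {
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  U <- u_of(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  mu <- nx * length(y) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-12))
}

# Build per-record choice data from counts: `a` choices of the
# alphabetically second variant, `b` of the first.
choices_from_counts <- function(a, b, trait = "hue",
                                variants = c("first", "second"),
                                species = "test sp") {
  tibble::tibble(
    species = species,
    trait = trait,
    block = "none",
    replicate = seq_len(a + b),
    variant_chosen = c(rep(variants[2], a), rep(variants[1], b))
  )
}

# Printed two-choice model rows used as inversion inputs (estimate, SE,
# Wald z at 3 printed decimals). The size row for the halictid species is
# excluded: its printed SE is inconsistent with its printed z.
printed_model_rows <- function() {
  tibble::tribble(
    ~test,                  ~species,        ~estimate, ~std_error, ~z_value,
    "hue",                  "L. villosulum",     1.099,      0.320,    3.430,
    "hue",                  "B. terrestris",     0.937,      0.155,    6.047,
    "hue",                  "O. bicornis",      -0.375,      0.392,   -0.957,
    "size",                 "B. terrestris",    -1.187,      0.269,   -4.409,
    "size",                 "O. bicornis",      -0.833,      0.379,   -2.199,
    "achromatic_contrast",  "O. bicornis",      -1.609,      0.447,   -3.599,
    "achromatic_contrast",  "B. terrestris",    -2.311,      0.303,   -7.635,
    "achromatic_contrast",  "L. villosulum",    -0.296,      0.245,   -1.208,
    "yellow_vs_light",      "L. villosulum",    -0.981,      0.391,   -2.509,
    "scent",                "O. bicornis",      -0.114,      0.144,   -0.791,
    "scent",                "B. terrestris",     0.128,      0.099,    1.289,
    "scent",                "L. villosulum",     0.310,      0.281,    1.105
  )
}

# Published antennal-response grid: responders out of n per species.
printed_eag_counts <- function() {
  list(
    "O. bicornis"   = list(n = 10, k = c(8, 7, 10, 10, 10, 10, 10, 10, 10, 10, 6, 5)),
    "B. terrestris" = list(n = 10, k = c(8, 4, 10, 9, 10, 10, 10, 10, 10, 9, 8, 9)),
    "L. villosulum" = list(n = 6,  k = c(4, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6))
  )
}
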
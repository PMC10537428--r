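# Shared fixture builders.  All synthetic data is generated in code; the
# only on-disk fixtures are the published reference tables under extdata.

make_bed <- function(layers = 1L) {
  scale_layers(bed_spec(Z = 115, A = 3.7, epsilon = 0.8367, W = 0.015),
               layers)
}

# noiseless (or noisy) logistic breakthrough curve with known (k, t_05)
logistic_curve <- function(k = 1, t_05 = 10, C0 = 2, F_mL = 1,
                           bed = make_bed(), noise_sd = 0, seed = NULL,
                           ...) {
  sp <- synthetic_spec("yoon_nelson", list(k_YN = k, t_05 = t_05),
                       C0 = C0, F_mL = F_mL, bed = bed,
                       noise_sd = noise_sd, seed = seed, ...)
  generate_breakthrough(sp)
}

# reference tables shipped with the package (published printed values)
ref_indicators <- function() {
  utils::read.csv(system.file("extdata", "lysozyme_indicators.csv",
                              package = "memchrom"), comment.char = "#")
}
ref_btc_models <- function() {
  utils::read.csv(system.file("extdata", "lysozyme_btc_models.csv",
                              package = "memchrom"), comment.char = "#")
}

expect_rel <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual / expected - 1)), tol))
}
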
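# Fixture builders shared across the suite. Everything is generated in
# code; no files ship with the package.

# A random valid band matrix (uses the ambient RNG; seed in the caller).
random_band_matrix <- function(n_primers = 2, bands_per_primer = 3,
                               n_treated = 2, assay = c("RAPD", "CREDRA")) {
  assay <- match.arg(assay)
  primers <- sprintf("OPR-%02d", seq_len(n_primers))
  bands <- data.frame(
    primer = rep(primers, each = bands_per_primer),
    band_id = rep(sprintf("b%02d", seq_len(bands_per_primer)), n_primers),
    size_bp = sample(c(NA, 100:1000), n_primers * bands_per_primer,
                     replace = TRUE))
  doses <- c(0, sort(sample(c(20, 40, 80, 160, 320, 640, 1280), n_treated)))
  samples <- data.frame(
    sample_id = ifelse(doses == 0, "control", paste0("Cu", doses)),
    dose_mg_per_L = doses, is_control = doses == 0)
  lanes <- if (assay == "RAPD") "X" else c("X", "H", "M")
  cols <- as.vector(t(outer(samples$sample_id, lanes, paste, sep = ":")))
  pres <- matrix(sample(0:1, nrow(bands) * length(cols), replace = TRUE),
                 nrow = nrow(bands), dimnames = list(NULL, cols))
  band_matrix(bands, samples, pres, assay = assay)
}

# A one-primer CRED-RA matrix whose single treated sample shows the given
# lane triplets (list of c(x, y, z)); the control shows all-present
# triplets so it stays classifiable.
credra_from_triplets <- function(triplets) {
  k <- length(triplets)
  bands <- data.frame(primer = "OPT-01", band_id = sprintf("b%02d", seq_len(k)),
                      size_bp = NA_integer_)
  samples <- data.frame(sample_id = c("control", "Cu20"),
                        dose_mg_per_L = c(0, 20),
                        is_control = c(TRUE, FALSE))
  tri <- do.call(rbind, triplets)
  pres <- cbind(`control:X` = rep(1L, k), `control:H` = rep(1L, k),
                `control:M` = rep(1L, k),
                `Cu20:X` = tri[, 1], `Cu20:H` = tri[, 2], `Cu20:M` = tri[, 3])
  band_matrix(bands, samples, pres, assay = "CREDRA")
}

# A RAPD matrix from explicit per-sample band-id sets for one primer.
rapd_from_sets <- function(control_bands, treated_bands, dose = 20) {
  ids <- sort(union(control_bands, treated_bands))
  bands <- data.frame(primer = "OPS-01", band_id = ids, size_bp = NA_integer_)
  samples <- data.frame(sample_id = c("control", "treated"),
                        dose_mg_per_L = c(0, dose),
                        is_control = c(TRUE, FALSE))
  pres <- cbind(`control:X` = as.integer(ids %in% control_bands),
                `treated:X` = as.integer(ids %in% treated_bands))
  band_matrix(bands, samples, pres, assay = "RAPD")
}

# Independent reference classifier: the published four-type truth table
# written as a literal lookup, kept separate from classify_band().
oracle_classify <- function(x, y, z) {
  if (x == 0) return("unclassifiable")
  if (y == 0 && z == 0) "I"
  else if (y == 0 && z == 1) "II"
  else if (y == 1 && z == 0) "III"
  else "IV"
}
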
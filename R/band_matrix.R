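#' Band-presence matrices for RAPD and CRED-RA assays
#'
#' A `band_matrix` is the universal exchange object of this package: the
#' binary presence/absence of named PCR bands over primers x samples x lanes,
#' as scored from gel profiles. Bands are dominant markers: a cell is 1
#' (band present) or 0 (band absent), never an allele dosage.
#'
#' Lanes distinguish the template the band was amplified from:
#' `X` = undigested genomic DNA, `H` = HpaII-digested, `M` = MspI-digested.
#' A RAPD matrix carries only `X` lanes; a CRED-RA matrix carries all three
#' for every sample, so each band contributes one lane triplet per sample.
#'
#' @param bands data.frame with columns `primer` (short uppercase primer
#'   name), `band_id` (unique within primer) and `size_bp` (positive
#'   fragment size in bp, or `NA`; informational only — band identity across
#'   samples is by `(primer, band_id)`, never by size).
#' @param samples data.frame with columns `sample_id`, `dose_mg_per_L`
#'   (non-negative) and `is_control` (logical; exactly one control, at dose 0).
#' @param presence integer matrix of 0/1 with one row per band and one
#'   column per sample-lane combination, columns named `"<sample_id>:<lane>"`.
#' @param assay `"RAPD"` (X lanes only) or `"CREDRA"` (X, H and M lanes for
#'   every sample).
#'
#' @return An object of class `band_matrix`.
#' @examples
#' bands <- data.frame(primer = "OPC-01", band_id = c("b1", "b2"),
#'                     size_bp = c(500L, NA))
#' samples <- data.frame(sample_id = c("control", "Cu20"),
#'                       dose_mg_per_L = c(0, 20),
#'                       is_control = c(TRUE, FALSE))
#' pres <- matrix(c(1L, 1L, 1L, 0L), nrow = 2,
#'                dimnames = list(NULL, c("control:X", "Cu20:X")))
#' m <- band_matrix(bands, samples, pres, assay = "RAPD")
#' @export
band_matrix <- function(bands, samples, presence, assay = c("RAPD", "CREDRA")) {
  assay <- match.arg(assay)
  bands <- as.data.frame(bands)
  samples <- as.data.frame(samples)
  storage.mode(presence) <- "integer"
  x <- structure(
    list(bands = bands, samples = samples, presence = presence,
         lanes = if (assay == "RAPD") "X" else c("X", "H", "M"),
         assay = assay),
    class = "band_matrix")
  validate_band_matrix(x)
}

#' Validate a band matrix
#'
#' Checks every structural invariant: binary cells, a complete
#' (band, sample, lane) grid, unique `(primer, band_id)` pairs, at least one
#' band per primer, exactly one control sample at dose 0, plausible fragment
#' sizes (50–5000 bp when given), and a lane set matching the assay.
#' Violations raise a condition of class `credra_validation_error`.
#'
#' @param x a `band_matrix`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_band_matrix <- function(x) {
  b <- x$bands; s <- x$samples; p <- x$presence
  need_b <- c("primer", "band_id", "size_bp")
  if (!all(need_b %in% names(b)))
    abort_credra("bands must have columns primer, band_id, size_bp",
                 "credra_validation_error")
  need_s <- c("sample_id", "dose_mg_per_L", "is_control")
  if (!all(need_s %in% names(s)))
    abort_credra("samples must have columns sample_id, dose_mg_per_L, is_control",
                 "credra_validation_error")
  if (nrow(b) == 0L)
    abort_credra("band matrix must contain at least one band",
                 "credra_validation_error")
  key <- paste(b$primer, b$band_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    abort_credra(sprintf("duplicate (primer, band_id): %s",
                         gsub("\r", "/", d)), "credra_validation_error")
  }
  if (any(grepl("[\t:]", c(b$primer, b$band_id, s$sample_id))))
    abort_credra("primer, band_id and sample_id must not contain tab or ':'",
                 "credra_validation_error")
  sz <- b$size_bp[!is.na(b$size_bp)]
  if (length(sz) && (any(sz < 50) || any(sz > 5000)))
    abort_credra("size_bp must lie in [50, 5000] when present",
                 "credra_validation_error")
  if (anyDuplicated(s$sample_id))
    abort_credra("duplicate sample_id", "credra_validation_error")
  if (sum(s$is_control) != 1L)
    abort_credra("exactly one sample must be flagged as control",
                 "credra_validation_error")
  if (s$dose_mg_per_L[s$is_control] != 0)
    abort_credra("the control sample must have dose 0",
                 "credra_validation_error")
  if (any(s$dose_mg_per_L < 0))
    abort_credra("doses must be non-negative", "credra_validation_error")
  want <- as.vector(t(outer(s$sample_id, x$lanes, paste, sep = ":")))
  if (!identical(sort(colnames(p)), sort(want)))
    abort_credra(sprintf(
      "presence columns must be exactly the %s lanes %s for every sample",
      x$assay, paste(x$lanes, collapse = "/")), "credra_validation_error")
  if (nrow(p) != nrow(b))
    abort_credra("presence must have one row per band",
                 "credra_validation_error")
  if (anyNA(p) || !all(p %in% c(0L, 1L)))
    abort_credra("presence values must be strictly binary (0/1)",
                 "credra_validation_error")
  invisible(x)
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("<band_matrix> %s assay: %d bands / %d primers, %d samples (control: %s)\n",
              x$assay, nrow(x$bands), length(unique(x$bands$primer)),
              nrow(x$samples), x$samples$sample_id[x$samples$is_control]))
  invisible(x)
}

# Presence column for one sample/lane, as an integer vector over bands.
lane_vector <- function(m, sample_id, lane) {
  col <- paste(sample_id, lane, sep = ":")
  if (!col %in% colnames(m$presence))
    abort_credra(sprintf("sample '%s' has no %s lane", sample_id, lane),
                 "credra_lookup_error")
  m$presence[, col]
}

control_id <- function(m) m$samples$sample_id[m$samples$is_control]

treated_ids <- function(m) {
  s <- m$samples[!m$samples$is_control, , drop = FALSE]
  s$sample_id[order(s$dose_mg_per_L)]
}
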
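#' Classify a CRED-RA lane triplet into a methylation type
#'
#' HpaII and MspI are isoschizomers of the CCGG site with different
#' methylation sensitivities, so the presence/absence of a band across the
#' undigested (`x`), HpaII (`y`) and MspI (`z`) lanes reveals the cytosine
#' methylation state of the CCGG sites inside the amplicon:
#'
#' | type | y (HpaII lane) | z (MspI lane) | meaning |
#' |------|----------------|---------------|---------|
#' | I    | 0 (digested)   | 0 (digested)  | non-methylation |
#' | II   | 0 (digested)   | 1 (blocked)   | semi-methylation (hemi-methylated external cytosine) |
#' | III  | 1 (blocked)    | 0 (digested)  | full-methylation (internal cytosine, both strands) |
#' | IV   | 1 (blocked)    | 1 (blocked)   | full-methylation (both cytosines, both strands) |
#'
#' A band must amplify from the undigested template to carry any
#' information: triplets with `x = 0` are `"unclassifiable"` regardless of
#' `y` and `z` (this is a value, not an error).
#'
#' @param x,y,z band presence (0/1) in the undigested, HpaII-digested and
#'   MspI-digested lanes. Vectorized; recycled to a common length.
#' @return character vector over `{"I","II","III","IV","unclassifiable"}`.
#' @seealso [methylation_pattern()] for the type-to-pattern label map.
#' @examples
#' classify_band(1, 0, 0)  # "I": both enzymes cut -> non-methylated
#' classify_band(1, 1, 1)  # "IV": both blocked -> fully methylated
#' @export
classify_band <- function(x, y, z) {
  k <- max(length(x), length(y), length(z))
  x <- rep_len(as.integer(x), k)
  y <- rep_len(as.integer(y), k)
  z <- rep_len(as.integer(z), k)
  if (anyNA(c(x, y, z)) || !all(c(x, y, z) %in% c(0L, 1L)))
    abort_credra("lane triplet values must be binary (0/1)",
                 "credra_validation_error")
  out <- rep("unclassifiable", k)
  amp <- x == 1L
  code <- 2L * y + z
  out[amp] <- c("I", "II", "III", "IV")[code[amp] + 1L]
  out
}

#' Methylation pattern label of a type
#'
#' Pure relabeling: Type I is non-methylation, Type II semi-methylation,
#' Types III and IV full-methylation; unclassifiable stays unclassifiable.
#'
#' @param type character vector of type labels as from [classify_band()].
#' @return character vector of pattern labels.
#' @export
methylation_pattern <- function(type) {
  map <- c(I = "non-methylation", II = "semi-methylation",
           III = "full-methylation", IV = "full-methylation",
           unclassifiable = "unclassifiable")
  bad <- setdiff(unique(type), names(map))
  if (length(bad))
    abort_credra(sprintf("unknown methylation type '%s'", bad[1L]),
                 "credra_lookup_error")
  unname(map[type])
}

#' Extract lane triplets for one sample
#'
#' @param matrix a CRED-RA [band_matrix()].
#' @param sample_id sample to extract.
#' @param primer restrict to one primer, or `"ALL"` (default).
#' @return data.frame with one row per band: `primer`, `band_id`, `x`, `y`,
#'   `z`.
#' @export
lane_triplets <- function(matrix, sample_id, primer = "ALL") {
  validate_band_matrix(matrix)
  if (matrix$assay != "CREDRA")
    abort_credra("lane triplets require a CRED-RA matrix (X/H/M lanes)",
                 "credra_validation_error")
  if (!sample_id %in% matrix$samples$sample_id)
    abort_credra(sprintf("unknown sample '%s'", sample_id),
                 "credra_lookup_error")
  keep <- if (identical(primer, "ALL")) rep(TRUE, nrow(matrix$bands))
          else matrix$bands$primer == primer
  if (!any(keep))
    abort_credra(sprintf("unknown primer '%s'", primer), "credra_lookup_error")
  data.frame(primer = matrix$bands$primer[keep],
             band_id = matrix$bands$band_id[keep],
             x = lane_vector(matrix, sample_id, "X")[keep],
             y = lane_vector(matrix, sample_id, "H")[keep],
             z = lane_vector(matrix, sample_id, "M")[keep])
}

#' Tally methylation types for one sample
#'
#' Applies [classify_band()] to every band's lane triplet and counts the
#' outcomes. The five tallies (I, II, III, IV, unclassifiable) always sum
#' to the number of bands evaluated.
#'
#' @inheritParams lane_triplets
#' @return named integer vector `c(I, II, III, IV, unclassifiable)`.
#' @export
type_counts <- function(matrix, sample_id, primer = "ALL") {
  t3 <- lane_triplets(matrix, sample_id, primer)
  cls <- classify_band(t3$x, t3$y, t3$z)
  cats <- c("I", "II", "III", "IV", "unclassifiable")
  counts <- table(factor(cls, levels = cats))
  setNames(as.integer(counts), cats)
}

classifiable_total <- function(counts) {
  need <- c("I", "II", "III", "IV")
  if (!all(need %in% names(counts)))
    abort_credra("counts must be named I, II, III, IV", "credra_validation_error")
  tot <- sum(counts[need])
  if (tot == 0)
    abort_credra("no classifiable bands (all triplets have x = 0)",
                 "credra_domain_error")
  tot
}

#' Methylation type percentages
#'
#' Each type's share of the classifiable bands: `100 * count / (I+II+III+IV)`.
#' Unclassifiable bands are excluded from the denominator, so the four
#' percentages sum to 100 exactly.
#'
#' @param counts named count vector as returned by [type_counts()].
#' @return named numeric `c(I, II, III, IV)` summing to 100.
#' @export
type_percentages <- function(counts) {
  tot <- classifiable_total(counts)
  100 * counts[c("I", "II", "III", "IV")] / tot
}

#' Methylation pattern ratios from type counts
#'
#' The three standard pattern ratios over classifiable bands
#' (`T = I + II + III + IV`):
#' * total methylation = `(II + III + IV) / T * 100`
#' * full methylation  = `(III + IV) / T * 100`
#' * semi methylation  = `II / T * 100`
#'
#' plus the non-methylation share `I / T * 100`. The identities
#' `total == full + semi` and `non + total == 100` hold exactly (total and
#' non are derived from full and semi so the identities are exact in
#' floating point, not merely close).
#'
#' @inheritParams type_percentages
#' @return named numeric `c(total, full, semi, non)`, in percent.
#' @export
pattern_ratios_from_counts <- function(counts) {
  tot <- classifiable_total(counts)
  full <- 100 * (counts[["III"]] + counts[["IV"]]) / tot
  semi <- 100 * counts[["II"]] / tot
  total <- full + semi
  c(total = total, full = full, semi = semi, non = 100 - total)
}

#' Methylation pattern ratios from printed type percentages
#'
#' Published CRED-RA tables usually print the four type percentages and the
#' total/full/semi ratios side by side; the ratio rows are the linear sums
#' of the printed type rows, with the denominator treated as 100. This
#' pathway reproduces such tables exactly even when the printed type
#' percentages do not sum to 100 (a common rounding artifact):
#' `total = pII + pIII + pIV`, `full = pIII + pIV`, `semi = pII`,
#' `non = pI`.
#'
#' @param p_i,p_ii,p_iii,p_iv type percentages (non-negative). Vectorized.
#' @return named numeric (or matrix when vectorized) with components
#'   `total`, `full`, `semi`, `non`, in percent.
#' @seealso [pattern_ratios_from_counts()] for the count-based formula
#'   pathway; the two agree whenever the percentage vector sums to 100.
#' @examples
#' pattern_ratios_from_percent_vector(2.60, 3.40, 5.10, 86.60)
#' @export
pattern_ratios_from_percent_vector <- function(p_i, p_ii, p_iii, p_iv) {
  if (any(c(p_i, p_ii, p_iii, p_iv) < 0))
    abort_credra("type percentages must be non-negative", "credra_domain_error")
  full <- p_iii + p_iv
  semi <- p_ii
  total <- full + semi
  out <- cbind(total = total, full = full, semi = semi, non = p_i)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Per-sample methylation summary table
#'
#' Builds the standard CRED-RA report: per sample, the four type
#' percentages and the total/full/semi/non pattern ratios, ordered by dose.
#'
#' Two aggregation modes across primers are available. `"average"` computes
#' type percentages and pattern ratios per primer and averages them with
#' equal primer weights (the "average rates" convention of published
#' tables); primers with no classifiable band for a sample are dropped from
#' that sample's average with a warning. `"pooled"` sums type counts over
#' all primers before applying the formulas (the count-faithful reading).
#'
#' @param matrix a CRED-RA [band_matrix()].
#' @param mode `"average"` (default) or `"pooled"`.
#' @return data.frame, one row per sample (control first, then by dose):
#'   `sample_id`, `dose_mg_per_L`, `type_I` .. `type_IV`, `total`, `full`,
#'   `semi`, `non`, `n_bands`, `n_unclassifiable`.
#' @export
methylation_table <- function(matrix, mode = c("average", "pooled")) {
  mode <- match.arg(mode)
  validate_band_matrix(matrix)
  if (matrix$assay != "CREDRA")
    abort_credra("methylation_table requires a CRED-RA matrix",
                 "credra_validation_error")
  s <- matrix$samples[order(matrix$samples$dose_mg_per_L,
                            !matrix$samples$is_control), ]
  primers <- unique(matrix$bands$primer)
  one_sample <- function(smp) {
    if (mode == "pooled") {
      counts <- type_counts(matrix, smp)
      pct <- type_percentages(counts)
      rat <- pattern_ratios_from_counts(counts)
    } else {
      per <- lapply(primers, function(p) type_counts(matrix, smp, primer = p))
      ok <- vapply(per, function(ct) sum(ct[c("I", "II", "III", "IV")]) > 0,
                   logical(1))
      if (!all(ok))
        warning(sprintf(
          "sample '%s': %d primer(s) with no classifiable band dropped from average",
          smp, sum(!ok)))
      if (!any(ok))
        abort_credra(sprintf("sample '%s' has no classifiable bands", smp),
                     "credra_domain_error")
      pct <- rowMeans(vapply(per[ok], type_percentages, numeric(4)))
      rat <- rowMeans(vapply(per[ok], pattern_ratios_from_counts, numeric(4)))
      counts <- Reduce(`+`, per)
    }
    data.frame(sample_id = smp,
               dose_mg_per_L = matrix$samples$dose_mg_per_L[
                 matrix$samples$sample_id == smp],
               type_I = pct[["I"]], type_II = pct[["II"]],
               type_III = pct[["III"]], type_IV = pct[["IV"]],
               total = rat[["total"]], full = rat[["full"]],
               semi = rat[["semi"]], non = rat[["non"]],
               n_bands = sum(counts),
               n_unclassifiable = counts[["unclassifiable"]])
  }
  out <- do.call(rbind, lapply(s$sample_id, one_sample))
  rownames(out) <- NULL
  out
}

#' Reshape a methylation summary into the published wide layout
#'
#' Rows are the metrics (Type I–IV percentages, then total/full/semi
#' ratios), columns the samples ordered by dose, values rounded half-up to
#' two decimals — the layout of a printed CRED-RA methylation table.
#'
#' @param tbl output of [methylation_table()].
#' @param digits decimals for half-up rounding (default 2).
#' @return data.frame with a `metric` column plus one column per sample.
#' @export
format_methylation_table <- function(tbl, digits = 2) {
  metrics <- c(type_I = "Type-I (%) (Non-methylation)",
               type_II = "Type-II (%)", type_III = "Type-III (%)",
               type_IV = "Type-IV (%)",
               total = "Total methylated bands ratio (%)",
               full = "Full-methylated bands ratio (%)",
               semi = "Semi-methylated bands ratio (%)")
  wide <- data.frame(metric = unname(metrics))
  for (i in seq_len(nrow(tbl)))
    wide[[tbl$sample_id[i]]] <-
      round_half_up(as.numeric(tbl[i, names(metrics)]), digits)
  wide
}
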
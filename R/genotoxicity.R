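#' Genomic template stability
#'
#' GTS is a qualitative genotoxicity index for dominant-marker profiles:
#' `(1 - a/n) * 100`, where `a` is the number of polymorphic bands (bands
#' that appeared or disappeared relative to the control profile) in a
#' treated sample and `n` is the total number of bands in the control.
#' A value of 100 means the treated profile is indistinguishable from the
#' control; heavier genomic damage drives it down.
#'
#' When `a > n` (more band changes than control bands — possible when many
#' new bands appear) the value is negative; it is returned as computed,
#' with a warning, rather than clamped.
#'
#' @param a number of polymorphic bands (appeared + disappeared), `>= 0`.
#' @param n total number of bands in the control profile, `>= 1`.
#' @return GTS as a percentage in `(-Inf, 100]`. Vectorized over `a`/`n`.
#' @seealso [polymorphism_percent()], with which it sums to 100 exactly.
#' @examples
#' gts_percent(a = 2, n = 16)  # 87.5
#' @export
gts_percent <- function(a, n) {
  check_a_n(a, n)
  if (any(a > n))
    warning("a > n: more polymorphic bands than control bands; GTS is negative")
  100 - polymorphism_percent(a, n)
}

#' Polymorphism percentage
#'
#' `(a/n) * 100`: the share of band changes (appearances plus
#' disappearances against the control profile) relative to the control band
#' count. The exact complement of [gts_percent()].
#'
#' @inheritParams gts_percent
#' @return polymorphism as a percentage, `>= 0`. Vectorized.
#' @examples
#' polymorphism_percent(a = 2, n = 16)  # 12.5
#' @export
polymorphism_percent <- function(a, n) {
  check_a_n(a, n)
  100 * a / n
}

check_a_n <- function(a, n) {
  if (any(n < 1))
    abort_credra("n must be >= 1 (no bands in the control profile)",
                 "credra_domain_error")
  if (any(a < 0))
    abort_credra("a must be non-negative", "credra_domain_error")
  invisible(NULL)
}

#' Count band appearances and disappearances against the control
#'
#' Compares a treated sample's undigested-template (X-lane) profile with the
#' control's, band by band: a band present in the treated sample but absent
#' in the control has *appeared*; one absent in the treated sample but
#' present in the control has *disappeared*. Only X lanes are compared, even
#' in CRED-RA matrices, because polymorphism is defined on the undigested
#' profile.
#'
#' @param matrix a [band_matrix()].
#' @param sample_id a treated (non-control) sample.
#' @param primer a primer name to restrict the comparison to, or `"ALL"`
#'   (default) for all primers pooled.
#' @return A one-row data.frame with columns `sample_id`, `primer`,
#'   `appeared`, `disappeared`, `a` (= appeared + disappeared) and `n`
#'   (control bands in scope).
#' @export
detect_polymorphisms <- function(matrix, sample_id, primer = "ALL") {
  validate_band_matrix(matrix)
  ctrl <- control_id(matrix)
  if (identical(sample_id, ctrl))
    abort_credra("sample_id is the control; compare a treated sample",
                 "credra_usage_error")
  if (!sample_id %in% matrix$samples$sample_id)
    abort_credra(sprintf("unknown sample '%s'", sample_id),
                 "credra_lookup_error")
  keep <- if (identical(primer, "ALL")) rep(TRUE, nrow(matrix$bands))
          else matrix$bands$primer == primer
  if (!any(keep))
    abort_credra(sprintf("unknown primer '%s'", primer), "credra_lookup_error")
  cx <- lane_vector(matrix, ctrl, "X")[keep]
  tx <- lane_vector(matrix, sample_id, "X")[keep]
  n <- sum(cx)
  if (n == 0L)
    abort_credra(sprintf("control has no bands for primer scope '%s'; n = 0",
                         primer), "credra_domain_error")
  appeared <- sum(tx == 1L & cx == 0L)
  disappeared <- sum(tx == 0L & cx == 1L)
  data.frame(sample_id = sample_id, primer = primer,
             appeared = appeared, disappeared = disappeared,
             a = appeared + disappeared, n = n)
}

#' Genotoxicity table over all treated samples
#'
#' Computes appearance/disappearance counts, polymorphism% and GTS% for
#' every (treated sample, primer) pair plus, per sample, an `ALL`-primer
#' aggregate in which `a` and `n` are summed over primers *before* the
#' formulas are applied (pooled counts, the count-consistent reading of the
#' per-dose index). Rows are ordered by dose.
#'
#' @param matrix a [band_matrix()] with at least the control's X lanes.
#' @param mode `"pooled"` (default) emits per-primer rows plus the pooled
#'   `ALL` aggregate; `"per-primer"` emits only the per-primer rows.
#' @return A data.frame with columns `sample_id`, `dose_mg_per_L`, `primer`,
#'   `appeared`, `disappeared`, `a`, `n`, `polymorphism_pct`, `gts_pct`;
#'   zero rows if the matrix has no treated samples.
#' @export
genotox_table <- function(matrix, mode = c("pooled", "per-primer")) {
  mode <- match.arg(mode)
  validate_band_matrix(matrix)
  treated <- treated_ids(matrix)
  primers <- unique(matrix$bands$primer)
  rows <- list()
  for (smp in treated) {
    per <- lapply(primers, function(p)
      detect_polymorphisms(matrix, smp, primer = p))
    rows <- c(rows, per)
    if (mode == "pooled") {
      agg <- do.call(rbind, per)
      rows <- c(rows, list(data.frame(
        sample_id = smp, primer = "ALL",
        appeared = sum(agg$appeared), disappeared = sum(agg$disappeared),
        a = sum(agg$a), n = sum(agg$n))))
    }
  }
  if (!length(rows)) {
    out <- data.frame(sample_id = character(), dose_mg_per_L = numeric(),
                      primer = character(), appeared = integer(),
                      disappeared = integer(), a = integer(), n = integer(),
                      polymorphism_pct = numeric(), gts_pct = numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  out$dose_mg_per_L <- matrix$samples$dose_mg_per_L[
    match(out$sample_id, matrix$samples$sample_id)]
  out$polymorphism_pct <- polymorphism_percent(out$a, out$n)
  out$gts_pct <- suppressWarnings(gts_percent(out$a, out$n))
  out <- out[order(out$dose_mg_per_L, out$sample_id,
                   out$primer != "ALL", out$primer), ]
  rownames(out) <- NULL
  out[, c("sample_id", "dose_mg_per_L", "primer", "appeared", "disappeared",
          "a", "n", "polymorphism_pct", "gts_pct")]
}
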
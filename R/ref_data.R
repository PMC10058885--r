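# Published reference values from a CRED-RA / RAPD study of safflower
# (Carthamus tinctorius) roots under copper stress (0-1280 mg/L CuSO4,
# 21 days). They serve two purposes: worked reference inputs for the
# percent-vector ratio pathway, and calibration of the simulator defaults.

.ref_doses <- c(0, 20, 40, 80, 160, 320, 640, 1280)

.ref_type_pct <- data.frame(
  dose_mg_per_L = .ref_doses,
  type_I   = c(2.60, 3.40, 4.10, 7.80, 4.40, 3.40, 2.40, 2.60),
  type_II  = c(3.40, 3.60, 3.90, 5.10, 5.60, 3.30, 2.60, 1.40),
  type_III = c(5.10, 7.20, 7.40, 6.60, 5.10, 4.30, 5.30, 5.90),
  type_IV  = c(86.60, 84.60, 83.00, 81.90, 81.60, 86.80, 86.00, 85.50),
  total    = c(95.10, 95.40, 94.30, 93.60, 92.30, 94.40, 93.90, 92.80),
  full     = c(91.70, 91.80, 90.40, 88.50, 86.70, 91.10, 91.30, 91.40),
  semi     = c(3.40, 3.60, 3.90, 5.10, 5.60, 3.30, 2.60, 1.40))

.ref_gts <- data.frame(
  dose_mg_per_L = c(20, 40, 80, 160, 320, 640, 1280),
  gts_pct = c(82.75, 88.90, 86.26, 83.90, 82.25, 84.60, 83.70))

.ref_primers <- data.frame(
  primer = c("OPC-01", "OPC-02", "OPC-04", "OPC-06", "OPC-07", "OPC-08",
             "OPC-09", "OPC-10", "OPC-11", "OPA-08"),
  sequence = c("TTCGAGCCAG", "GTGAGGCGTC", "CCGCATCTAC", "GAACGGACTC",
               "GTCCCGACGA", "TGGACCGGTG", "CTCACCGTCC", "TGTCTGGGTG",
               "AAAGCTGCGG", "GTGACGTAGG"),
  polymorphism_pct = c(16.90, 14.40, 36.40, 52.90, 56.80, 53.00, 59.70,
                       54.10, 55.90, 32.50))

#' Reference methylation type percentages (safflower under copper)
#'
#' Per-dose average methylation type percentages (Type I–IV) and the
#' total/full/semi pattern-ratio rows from a published CRED-RA assay of
#' safflower roots after 21 days of copper exposure (control plus 20–1280
#' mg/L). The type rows are the input of the percent-vector ratio pathway;
#' the ratio rows are its expected output. Note the printed type
#' percentages do not sum exactly to 100 (e.g. the control column sums to
#' 97.70), which is why the percent-vector pathway treats the denominator
#' as 100 (see [pattern_ratios_from_percent_vector()]).
#'
#' These values also calibrate the per-dose methylation-state probabilities
#' of [sim_config()] (normalized to sum to 1).
#'
#' @return data.frame with `dose_mg_per_L`, `type_I`..`type_IV`, `total`,
#'   `full`, `semi` (all percent).
#' @export
ref_type_percentages <- function() .ref_type_pct

#' Reference genomic template stability rates (safflower under copper)
#'
#' Per-dose GTS percentages from the RAPD arm of the same study; used to
#' calibrate the default per-dose band-loss and band-gain rates of
#' [sim_config()] so that the expected simulated polymorphism equals
#' `100 - GTS` at each dose.
#'
#' @return data.frame with `dose_mg_per_L` and `gts_pct`.
#' @export
ref_gts_rates <- function() .ref_gts

#' Reference RAPD primer panel
#'
#' The decamer primer panel (names, 5'→3' sequences, observed polymorphism
#' rates) of the reference study. The simulator labels its primers with
#' these names; the sequences are informational metadata (they are not used
#' to construct amplicons, since several contain CCGG-adjacent motifs that
#' would confound the controlled site placement).
#'
#' @return data.frame with `primer`, `sequence`, `polymorphism_pct`.
#' @export
ref_rapd_primers <- function() .ref_primers
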
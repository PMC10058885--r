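#' Simulation configuration for synthetic CRED-RA / RAPD experiments
#'
#' Defines a ground-truthed in-silico experiment: a panel of RAPD primers
#' each amplifying a set of anonymous bands (amplicons carrying CCGG
#' sites), one control and a ladder of treated samples, per-dose
#' probabilities of the four CCGG methylation states, and per-dose
#' priming-site mutation rates (band loss and band gain) that create RAPD
#' polymorphism.
#'
#' The four methylation states mirror the four band types they produce at
#' a single CCGG site: `U` unmethylated (HpaII and MspI both cut → Type I),
#' `HE` hemi-methylated external cytosine (HpaII cuts, MspI blocked →
#' Type II), `IF` internal cytosine methylated on both strands (HpaII
#' blocked, MspI cuts → Type III), `FF` fully methylated (both blocked →
#' Type IV).
#'
#' Defaults emulate the reference safflower–copper study: the dose ladder
#' is 0 (control) plus 20–1280 mg/L; per-dose `state_probs` are the
#' reference type percentages ([ref_type_percentages()]) normalized to sum
#' to 1; `band_loss_prob` and `band_gain_rate` split the reference
#' polymorphism deficit `(100 - GTS)/100` ([ref_gts_rates()]) evenly
#' between band loss and band gain, so the expected polymorphism% at dose
#' `d` equals `100 - GTS(d)`. The default panel is 6 primers x 10 bands
#' (the CRED-RA primer count of the reference study and a typical RAPD
#' band yield per decamer primer).
#'
#' @param n_primers number of primers in the panel.
#' @param bands_per_primer bands amplified per primer (before mutation).
#' @param doses dose ladder in mg/L; must contain 0 (the control) exactly
#'   once.
#' @param state_probs numeric matrix, one row per dose (same order as
#'   `doses`), columns `U`, `HE`, `IF`, `FF`; each row sums to 1 (within
#'   1e-12). `NULL` uses the reference-calibrated default (requires all
#'   doses to be reference doses).
#' @param band_loss_prob per-dose probability that a band is lost from a
#'   treated sample (priming-site mutation); recycled over doses; the
#'   control never loses bands. `NULL` uses the reference default.
#' @param band_gain_rate per-dose expected number of de novo bands per
#'   primer (Poisson); `NULL` uses the reference default.
#' @param sites_per_amplicon number of CCGG sites engineered into every
#'   amplicon (default 1, which makes band type and site state a
#'   bijection).
#' @param amplicon_length two integers: uniform range of amplicon lengths
#'   in bp (default 100–1000, the usual RAPD sizing window).
#' @param seed integer seed; every simulator draw flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_primers = 6, bands_per_primer = 10,
                       doses = c(0, 20, 40, 80, 160, 320, 640, 1280),
                       state_probs = NULL, band_loss_prob = NULL,
                       band_gain_rate = NULL, sites_per_amplicon = 1,
                       amplicon_length = c(100, 1000), seed = 1) {
  if (n_primers < 1 || bands_per_primer < 0)
    abort_credra("n_primers must be >= 1 and bands_per_primer >= 0",
                 "credra_config_error")
  if (anyDuplicated(doses) || sum(doses == 0) != 1 || any(doses < 0))
    abort_credra("doses must be distinct, non-negative, and include 0 exactly once",
                 "credra_config_error")
  ref_t <- ref_type_percentages()
  ref_g <- ref_gts_rates()
  if (is.null(state_probs)) {
    if (!all(doses %in% ref_t$dose_mg_per_L))
      abort_credra("no default state_probs for non-reference doses; supply state_probs",
                   "credra_config_error")
    i <- match(doses, ref_t$dose_mg_per_L)
    raw <- as.matrix(ref_t[i, c("type_I", "type_II", "type_III", "type_IV")])
    state_probs <- raw / rowSums(raw)
    colnames(state_probs) <- c("U", "HE", "IF", "FF")
  }
  state_probs <- as.matrix(state_probs)
  if (nrow(state_probs) != length(doses) ||
      !identical(colnames(state_probs), c("U", "HE", "IF", "FF")))
    abort_credra("state_probs must have one row per dose and columns U, HE, IF, FF",
                 "credra_config_error")
  if (any(state_probs < 0) || any(state_probs > 1) ||
      any(abs(rowSums(state_probs) - 1) > 1e-12))
    abort_credra("each state_probs row must be probabilities summing to 1",
                 "credra_config_error")
  deficit <- function(d) {  # expected polymorphism fraction at dose d
    if (d == 0) return(0)
    j <- match(d, ref_g$dose_mg_per_L)
    if (is.na(j))
      abort_credra("no default mutation rates for non-reference doses; supply band_loss_prob and band_gain_rate",
                   "credra_config_error")
    (100 - ref_g$gts_pct[j]) / 100
  }
  if (is.null(band_loss_prob))
    band_loss_prob <- vapply(doses, deficit, numeric(1)) / 2
  if (is.null(band_gain_rate))
    band_gain_rate <- vapply(doses, deficit, numeric(1)) / 2 * bands_per_primer
  band_loss_prob <- rep_len(band_loss_prob, length(doses))
  band_gain_rate <- rep_len(band_gain_rate, length(doses))
  if (any(band_loss_prob < 0) || any(band_loss_prob > 1) ||
      any(band_gain_rate < 0))
    abort_credra("band_loss_prob must be in [0,1], band_gain_rate >= 0",
                 "credra_config_error")
  if (sites_per_amplicon < 0)
    abort_credra("sites_per_amplicon must be >= 0", "credra_config_error")
  if (length(amplicon_length) != 2 || amplicon_length[1] > amplicon_length[2] ||
      amplicon_length[1] < 8 * max(1, sites_per_amplicon))
    abort_credra("amplicon_length must be an increasing pair long enough for the requested sites",
                 "credra_config_error")
  ord <- order(doses)
  structure(list(
    n_primers = as.integer(n_primers),
    bands_per_primer = as.integer(bands_per_primer),
    doses = doses[ord],
    state_probs = state_probs[ord, , drop = FALSE],
    band_loss_prob = band_loss_prob[ord],
    band_gain_rate = band_gain_rate[ord],
    sites_per_amplicon = as.integer(sites_per_amplicon),
    amplicon_length = as.integer(amplicon_length),
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d primers x %d bands, %d doses, %d CCGG site(s)/amplicon, seed %d\n",
              x$n_primers, x$bands_per_primer, length(x$doses),
              x$sites_per_amplicon, x$seed))
  invisible(x)
}

sim_primer_names <- function(n) {
  ref <- ref_rapd_primers()$primer
  if (n <= length(ref)) ref[seq_len(n)]
  else c(ref, sprintf("OPX-%02d", seq_len(n - length(ref))))
}

sim_sample_ids <- function(doses) {
  ifelse(doses == 0, "control", paste0("Cu", format(doses, trim = TRUE,
                                                    scientific = FALSE)))
}

# Random DNA of the given length with exactly n_sites non-overlapping CCGG
# motifs and no accidental extras. Accidental motifs are scrubbed by
# redrawing one internal base; engineered motifs are then overwritten at
# spaced positions (gap >= 4, which cannot create a new boundary-spanning
# CCGG).
make_amplicon_seq <- function(len, n_sites) {
  bases <- c("A", "C", "G", "T")
  for (try in 1:50) {
    s <- sample(bases, len, replace = TRUE)
    for (iter in 1:100) {
      hits <- gregexpr("CCGG", paste(s, collapse = ""), fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) break
      for (h in hits) s[h + 1L] <- sample(c("A", "G", "T"), 1L)
    }
    if (gregexpr("CCGG", paste(s, collapse = ""), fixed = TRUE)[[1L]][1L] != -1L)
      next
    starts <- integer(0)
    if (n_sites > 0) {
      repeat {
        starts <- sort(sample.int(len - 3L, n_sites))
        if (n_sites < 2L || all(diff(starts) >= 4L)) break
      }
      for (st in starts) s[st:(st + 3L)] <- c("C", "C", "G", "G")
    }
    seq <- paste(s, collapse = "")
    hits <- gregexpr("CCGG", seq, fixed = TRUE)[[1L]]
    found <- if (hits[1L] == -1L) 0L else length(hits)
    if (found == n_sites && identical(as.integer(hits)[seq_len(n_sites)],
                                      starts) || n_sites == 0L && found == 0L)
      return(list(seq = seq, sites = starts))
  }
  abort_credra("amplicon construction failed after bounded retries",
               "credra_generation_error")
}

#' Generate synthetic amplicon sequences
#'
#' One random amplicon per (primer, band): length uniform over the
#' configured range, composed of i.i.d. bases, carrying exactly
#' `sites_per_amplicon` CCGG motifs and no accidental extra occurrence.
#' Consumes the global RNG stream (seed it, or call via
#' [simulate_experiment()] which seeds from the config).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `primer`, `band_id`, `size_bp`, `seq` and a
#'   list-column `sites` of 1-based CCGG start offsets; zero rows when
#'   `bands_per_primer` is 0.
#' @export
generate_amplicons <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  primers <- sim_primer_names(cfg$n_primers)
  n <- cfg$n_primers * cfg$bands_per_primer
  if (n == 0L)
    return(data.frame(primer = character(), band_id = character(),
                      size_bp = integer(), seq = character(),
                      sites = I(list())))
  lens <- sample(seq(cfg$amplicon_length[1L], cfg$amplicon_length[2L]),
                 n, replace = TRUE)
  made <- lapply(lens, make_amplicon_seq, n_sites = cfg$sites_per_amplicon)
  data.frame(
    primer = rep(primers, each = cfg$bands_per_primer),
    band_id = rep(sprintf("b%03d", seq_len(cfg$bands_per_primer)),
                  times = cfg$n_primers),
    size_bp = lens,
    seq = vapply(made, `[[`, character(1), "seq"),
    sites = I(lapply(made, `[[`, "sites")))
}

#' Assign methylation states and mutation events (the hidden truth)
#'
#' For every sample, each CCGG site of each amplicon draws a methylation
#' state independently from that dose's `state_probs` (the control uses the
#' dose-0 vector). Treated samples then draw band-loss events (Bernoulli
#' per band) and band-gain events (Poisson per primer); the control is the
#' mutation-free reference. Draw order is fixed — states by sample, then
#' losses, then gains — so partial re-runs reproduce.
#'
#' @param cfg a [sim_config()].
#' @param amplicons output of [generate_amplicons()].
#' @return An object of class `synthetic_truth`: list with `samples`
#'   (sample_id, dose, is_control), `states` (long data.frame: sample_id,
#'   primer, band_id, site_index, state), `losses` (sample_id, primer,
#'   band_id, lost) and `gains` (sample_id, primer, band_id).
#' @export
assign_states <- function(cfg, amplicons) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_sample_ids(cfg$doses)
  samples <- data.frame(sample_id = ids, dose_mg_per_L = cfg$doses,
                        is_control = cfg$doses == 0)
  n_bands <- nrow(amplicons)
  spa <- cfg$sites_per_amplicon
  states <- NULL
  if (n_bands > 0 && spa > 0) {
    per_sample <- lapply(seq_along(ids), function(j)
      sample(c("U", "HE", "IF", "FF"), n_bands * spa, replace = TRUE,
             prob = cfg$state_probs[j, ]))
    states <- data.frame(
      sample_id = rep(ids, each = n_bands * spa),
      primer = rep(rep(amplicons$primer, each = spa), times = length(ids)),
      band_id = rep(rep(amplicons$band_id, each = spa), times = length(ids)),
      site_index = rep(rep(seq_len(spa), times = n_bands), times = length(ids)),
      state = unlist(per_sample, use.names = FALSE))
  } else {
    states <- data.frame(sample_id = character(), primer = character(),
                         band_id = character(), site_index = integer(),
                         state = character())
  }
  losses <- gains <- list()
  for (j in seq_along(ids)) {
    if (samples$is_control[j] || n_bands == 0) next
    lost <- stats::rbinom(n_bands, 1L, cfg$band_loss_prob[j]) == 1L
    losses[[length(losses) + 1L]] <- data.frame(
      sample_id = ids[j], primer = amplicons$primer,
      band_id = amplicons$band_id, lost = lost)
    for (p in unique(amplicons$primer)) {
      k <- stats::rpois(1L, cfg$band_gain_rate[j])
      if (k > 0)
        gains[[length(gains) + 1L]] <- data.frame(
          sample_id = ids[j], primer = p,
          band_id = sprintf("g_%s_%02d", ids[j], seq_len(k)))
    }
  }
  empty_l <- data.frame(sample_id = character(), primer = character(),
                        band_id = character(), lost = logical())
  empty_g <- data.frame(sample_id = character(), primer = character(),
                        band_id = character())
  structure(list(
    samples = samples,
    states = states,
    losses = if (length(losses)) do.call(rbind, losses) else empty_l,
    gains = if (length(gains)) do.call(rbind, gains) else empty_g),
    class = "synthetic_truth")
}

#' In-silico digestion and banding
#'
#' Turns the hidden truth into an observable CRED-RA band matrix by the
#' enzyme rules: HpaII cleaves a CCGG site in state `U` or `HE` and is
#' blocked by `IF`/`FF`; MspI cleaves `U` or `IF` and is blocked by
#' `HE`/`FF`. A single cleavable site anywhere in the amplicon kills the
#' band in that enzyme's lane (a cut template cannot amplify the full
#' product). The undigested X lane shows the band unless a band-loss
#' mutation removed it, in which case all three lanes are empty. Gained
#' (de novo) bands appear only in their own sample's X lane and are cut by
#' both enzymes (unmethylated novel loci).
#'
#' @param truth a `synthetic_truth` from [assign_states()].
#' @param amplicons the matching [generate_amplicons()] output.
#' @param cfg the [sim_config()] both were generated under.
#' @return A validated CRED-RA [band_matrix()].
#' @export
digest_and_band <- function(truth, amplicons, cfg) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "sim_config"))
  ids <- truth$samples$sample_id
  n_bands <- nrow(amplicons)
  if (n_bands == 0)
    abort_credra("no amplicons to band", "credra_validation_error")
  bands <- amplicons[, c("primer", "band_id", "size_bp")]
  gains <- truth$gains
  if (nrow(gains))
    bands <- rbind(bands, data.frame(primer = gains$primer,
                                     band_id = gains$band_id,
                                     size_bp = NA_integer_))
  lanes <- as.vector(t(outer(ids, c("X", "H", "M"), paste, sep = ":")))
  pres <- matrix(0L, nrow = nrow(bands), ncol = length(lanes),
                 dimnames = list(NULL, lanes))
  bkey <- paste(bands$primer, bands$band_id)
  akey <- paste(amplicons$primer, amplicons$band_id)
  hpa_cut <- c(U = TRUE, HE = TRUE, IF = FALSE, FF = FALSE)
  msp_cut <- c(U = TRUE, HE = FALSE, IF = TRUE, FF = FALSE)
  for (smp in ids) {
    st <- truth$states[truth$states$sample_id == smp, , drop = FALSE]
    skey <- paste(st$primer, st$band_id)
    any_hpa <- tapply(hpa_cut[st$state], skey, any)
    any_msp <- tapply(msp_cut[st$state], skey, any)
    x <- rep(1L, n_bands)
    lost <- truth$losses[truth$losses$sample_id == smp, , drop = FALSE]
    if (nrow(lost))
      x[match(paste(lost$primer, lost$band_id)[lost$lost], akey)] <- 0L
    cut_h <- unname(any_hpa[akey]); cut_m <- unname(any_msp[akey])
    # site-free amplicons carry no CCGG: neither enzyme can cut them
    cut_h[is.na(cut_h)] <- FALSE
    cut_m[is.na(cut_m)] <- FALSE
    h <- as.integer(x == 1L & !cut_h)
    m <- as.integer(x == 1L & !cut_m)
    pres[seq_len(n_bands), paste(smp, "X", sep = ":")] <- x
    pres[seq_len(n_bands), paste(smp, "H", sep = ":")] <- h
    pres[seq_len(n_bands), paste(smp, "M", sep = ":")] <- m
    own <- which(gains$sample_id == smp)
    if (length(own))
      pres[n_bands + own, paste(smp, "X", sep = ":")] <- 1L
  }
  band_matrix(bands, truth$samples, pres, assay = "CREDRA")
}

#' Project a CRED-RA matrix onto its RAPD view
#'
#' Keeps only the undigested X lanes, yielding the RAPD matrix on which
#' genotoxicity statistics are defined.
#'
#' @param matrix a CRED-RA [band_matrix()].
#' @return a RAPD [band_matrix()].
#' @export
as_rapd <- function(matrix) {
  validate_band_matrix(matrix)
  cols <- grep(":X$", colnames(matrix$presence), value = TRUE)
  band_matrix(matrix$bands, matrix$samples,
              matrix$presence[, cols, drop = FALSE], assay = "RAPD")
}

#' Write the hidden simulation truth to TSV
#'
#' One row per (sample, band, site) with the drawn methylation state, plus
#' the band-loss flag and rows for gained bands (state `NA`, `gained = 1`).
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  st <- truth$states
  lost_key <- paste(truth$losses$sample_id, truth$losses$primer,
                    truth$losses$band_id)
  lost_map <- setNames(as.integer(truth$losses$lost), lost_key)
  lost <- lost_map[paste(st$sample_id, st$primer, st$band_id)]
  lost[is.na(lost)] <- 0L
  out <- data.frame(sample_id = st$sample_id, primer = st$primer,
                    band_id = st$band_id, site_index = st$site_index,
                    state = st$state, lost = lost, gained = 0L)
  if (nrow(truth$gains))
    out <- rbind(out, data.frame(
      sample_id = truth$gains$sample_id, primer = truth$gains$primer,
      band_id = truth$gains$band_id, site_index = NA_integer_,
      state = NA_character_, lost = 0L, gained = 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a full synthetic experiment
#'
#' Seeds the RNG from the config and composes the generator end to end
#' (amplicons, then states, then mutations — a fixed draw order), writing
#' `rapd.tsv` and `credra.tsv` (band-matrix dialect), `truth.tsv` and
#' `amplicons.fasta` (headers `>primer|band_id|size`) into `out_dir`.
#' Identical configs produce bit-identical files.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   all file output.
#' @return Invisibly, a list with `config`, `amplicons`, `truth`, `credra`,
#'   `rapd` and (when written) `paths`.
#' @export
simulate_experiment <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  amplicons <- generate_amplicons(cfg)
  truth <- assign_states(cfg, amplicons)
  credra <- digest_and_band(truth, amplicons, cfg)
  rapd <- as_rapd(credra)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(rapd = file.path(out_dir, "rapd.tsv"),
                  credra = file.path(out_dir, "credra.tsv"),
                  truth = file.path(out_dir, "truth.tsv"),
                  fasta = file.path(out_dir, "amplicons.fasta"))
    write_band_matrix(rapd, paths$rapd)
    write_band_matrix(credra, paths$credra)
    write_truth(truth, paths$truth)
    seqs <- Biostrings::DNAStringSet(setNames(
      amplicons$seq,
      sprintf("%s|%s|%d", amplicons$primer, amplicons$band_id,
              amplicons$size_bp)))
    Biostrings::writeXStringSet(seqs, paths$fasta)
  }
  invisible(list(config = cfg, amplicons = amplicons, truth = truth,
                 credra = credra, rapd = rapd, paths = paths))
}
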
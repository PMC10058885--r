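#' Read a band-presence matrix from TSV
#'
#' Parses the band-matrix TSV dialect: optional `#` comment lines before the
#' header carry per-sample metadata (`# sample <id> dose=<d> control=<0|1>`
#' and `# assay=<RAPD|CREDRA>`), then a header row
#' `primer  band_id  size_bp  <sample_id>:<lane> ...` with lane in X/H/M,
#' then one row per band with literal `0`/`1` cells (`size_bp` may be `NA`).
#'
#' @param path path to a TSV file written by [write_band_matrix()] (or by
#'   any scorer emitting the same dialect).
#' @param assay expected assay kind; `NULL` (default) accepts whatever the
#'   file declares, otherwise a mismatch is an error.
#' @return A validated [band_matrix()].
#' @export
read_band_matrix <- function(path, assay = NULL) {
  if (!file.exists(path))
    abort_credra(sprintf("file not found: %s", path), "credra_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^#", lines)
  body <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body))
    abort_credra(sprintf("%s: no header row found", path), "credra_parse_error")

  meta <- lines[is_comment & seq_along(lines) < body[1L]]
  file_assay <- sub("^#\\s*assay=", "", grep("^#\\s*assay=", meta, value = TRUE))
  smeta <- grep("^#\\s*sample\\s", meta, value = TRUE)
  if (!length(smeta))
    abort_credra(sprintf("%s: no '# sample' metadata lines before header", path),
                 "credra_parse_error")
  sm <- lapply(smeta, function(l) {
    f <- strsplit(trimws(sub("^#\\s*sample\\s+", "", l)), "\t")[[1L]]
    if (length(f) != 3L || !grepl("^dose=", f[2L]) || !grepl("^control=", f[3L]))
      abort_credra(sprintf("%s: malformed sample metadata line: %s", path, l),
                   "credra_parse_error")
    data.frame(sample_id = f[1L],
               dose_mg_per_L = as.numeric(sub("^dose=", "", f[2L])),
               is_control = sub("^control=", "", f[3L]) == "1")
  })
  samples <- do.call(rbind, sm)

  hline <- body[1L]
  header <- strsplit(lines[hline], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L || !identical(header[1:3], c("primer", "band_id", "size_bp")))
    abort_credra(sprintf(
      "%s: line %d: header must start with 'primer\tband_id\tsize_bp'",
      path, hline), "credra_parse_error")
  lane_cols <- header[-(1:3)]
  if (!all(grepl("^[^:]+:[XHM]$", lane_cols)))
    abort_credra(sprintf("%s: line %d: lane columns must be '<sample>:<X|H|M>'",
                         path, hline), "credra_parse_error")

  rows <- lines[body[-1L]]
  cells <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    abort_credra(sprintf("%s: line %d: expected %d columns, found %d",
                         path, body[-1L][bad[1L]], length(header),
                         lengths(cells)[bad[1L]]), "credra_parse_error")
  if (!length(rows))
    abort_credra(sprintf("%s: no band rows", path), "credra_parse_error")
  tab <- do.call(rbind, cells)
  pres_chr <- tab[, -(1:3), drop = FALSE]
  nonbin <- which(!pres_chr %in% c("0", "1"))
  if (length(nonbin)) {
    idx <- arrayInd(nonbin[1L], dim(pres_chr))
    abort_credra(sprintf(
      "%s: non-binary cell '%s' at band row %d, column '%s'",
      path, pres_chr[nonbin[1L]], idx[1L], lane_cols[idx[2L]]),
      "credra_validation_error")
  }
  presence <- matrix(as.integer(pres_chr), nrow = nrow(tab),
                     dimnames = list(NULL, lane_cols))
  bands <- data.frame(primer = tab[, 1L], band_id = tab[, 2L],
                      size_bp = suppressWarnings(as.integer(tab[, 3L])))
  if (any(!is.na(tab[, 3L]) & tab[, 3L] != "NA" & is.na(bands$size_bp)))
    abort_credra(sprintf("%s: size_bp cells must be integers or NA", path),
                 "credra_parse_error")

  lane_kinds <- unique(sub("^[^:]+:", "", lane_cols))
  inferred <- if (setequal(lane_kinds, "X")) "RAPD" else "CREDRA"
  declared <- if (length(file_assay)) file_assay[1L] else inferred
  if (!is.null(assay) && !identical(declared, assay))
    abort_credra(sprintf("%s: file is a %s matrix, expected %s",
                         path, declared, assay), "credra_validation_error")
  band_matrix(bands, samples, presence, assay = declared)
}

#' Write a band-presence matrix to TSV
#'
#' Inverse of [read_band_matrix()]: the written file re-reads to a matrix
#' with bit-identical presence values, in the same band, sample and lane
#' order. The matrix is validated before anything is written.
#'
#' @param matrix a valid [band_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(matrix, path) {
  validate_band_matrix(matrix)
  s <- matrix$samples
  con_lines <- c(
    sprintf("# assay=%s", matrix$assay),
    sprintf("# sample\t%s\tdose=%s\tcontrol=%d",
            s$sample_id, format(s$dose_mg_per_L, scientific = FALSE, trim = TRUE),
            as.integer(s$is_control)))
  lane_cols <- colnames(matrix$presence)  # order-preserving round trip
  header <- paste(c("primer", "band_id", "size_bp", lane_cols), collapse = "\t")
  pres <- matrix$presence[, lane_cols, drop = FALSE]
  size <- ifelse(is.na(matrix$bands$size_bp), "NA",
                 as.character(matrix$bands$size_bp))
  rows <- paste(matrix$bands$primer, matrix$bands$band_id, size,
                apply(pres, 1L, paste, collapse = "\t"), sep = "\t")
  ok <- tryCatch({
    writeLines(c(con_lines, header, rows), path, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_credra(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                 "credra_io_error")
  invisible(path)
}
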
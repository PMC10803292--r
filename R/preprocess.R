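# Exclusion rules and segmentation.
#
# Records are filtered by fixed cohort rules: drop patients under
# 18, unconfirmed records and sampling rates under 500 Hz, then cut each
# record into consecutive non-overlapping 2.5 s windows of 1250 samples with
# no filtering or baseline correction.

#' Apply the cohort exclusion rules to a dataset manifest
#'
#' Retains records with age of at least 18, `confirmed = TRUE`, sampling
#' rate of at least 500 Hz and a label other than `"other"`. Rules are applied in that
#' fixed order and each excluded record is counted once, under the first
#' rule it violates. Records with missing age or confirmed metadata are
#' excluded under a separate `missing_metadata` category checked first.
#'
#' @param manifest Data.frame as returned by [cohort_manifest()].
#' @return List with `manifest` (retained rows) and `report` (data.frame of
#'   per-rule exclusion counts, including a `retained` row).
#' @export
apply_exclusions <- function(manifest) {
  req <- c("age", "confirmed", "fs", "label")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  n <- nrow(manifest)
  reason <- rep(NA_character_, n)
  miss <- is.na(manifest$age) | is.na(manifest$confirmed)
  reason[miss] <- "missing_metadata"
  pick <- function(cond, tag) {
    sel <- is.na(reason) & cond
    reason[sel] <<- tag
  }
  pick(manifest$age < 18, "age_under_18")
  pick(!manifest$confirmed, "unconfirmed")
  pick(manifest$fs < 500, "sampling_rate_under_500")
  pick(manifest$label == "other", "label_other")
  keep <- is.na(reason)
  rules <- c("age_under_18", "unconfirmed", "sampling_rate_under_500",
             "label_other", "missing_metadata")
  report <- data.frame(
    rule = c(rules, "retained"),
    n = c(vapply(rules, function(r) sum(reason == r, na.rm = TRUE), 0L),
          sum(keep)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(manifest = manifest[keep, , drop = FALSE], report = report)
}

#' Segment a record into fixed-length windows
#'
#' Cuts non-overlapping consecutive windows of `round(window_s * fs)` samples
#' starting at sample 1; a trailing remainder shorter than one window is
#' dropped. Amplitudes are passed through bit-exactly: no filtering,
#' detrending or baseline correction. A 10 s record at 500 Hz yields 4
#' windows of 1250 samples.
#'
#' @param record An `ecg_record`.
#' @param window_s Window length in seconds (default 2.5).
#' @return List of `ecg_segment` objects (each with `record_id`,
#'   0-based `window_index`, `signals` (leads x samples), `label`, `fs`).
#'   A record shorter than one window gives an empty list with a warning.
#' @export
segment_record <- function(record, window_s = 2.5) {
  w <- round(window_s * record$fs)
  N <- ncol(record$signals)
  n_win <- N %/% w
  if (n_win == 0) {
    warning("record ", record$record_id, " shorter than one window; no segments")
    return(list())
  }
  lapply(seq_len(n_win) - 1L, function(i) {
    seg <- list(record_id = record$record_id,
                patient_id = record$patient_id,
                window_index = i,
                signals = record$signals[, (i * w + 1L):((i + 1L) * w),
                                         drop = FALSE],
                label = record$label,
                fs = record$fs)
    class(seg) <- "ecg_segment"
    seg
  })
}

#' Segment every record of a cohort
#'
#' @param records List of `ecg_record` objects.
#' @param window_s Window length in seconds.
#' @return List with `segments` (flat list of `ecg_segment`) and `meta`
#'   (data.frame: `record_id`, `patient_id`, `label`, `window_index`).
#' @export
segment_cohort <- function(records, window_s = 2.5) {
  segs <- unlist(lapply(records, segment_record, window_s = window_s),
                 recursive = FALSE)
  meta <- data.frame(
    record_id = vapply(segs, `[[`, "", "record_id"),
    patient_id = vapply(segs, `[[`, "", "patient_id"),
    label = vapply(segs, `[[`, "", "label"),
    window_index = vapply(segs, `[[`, 0L, "window_index"),
    stringsAsFactors = FALSE
  )
  list(segments = segs, meta = meta)
}

#' Patient-disjoint split assignment
#'
#' Assigns each element to `"train"` or `"test"` such that all segments of a
#' patient fall on the same side (no patient spans the split).
#'
#' @param patient_ids Character vector, one entry per segment.
#' @param test_frac Fraction of patients assigned to the test side.
#' @return Character vector (`"train"`/`"test"`) aligned with `patient_ids`.
#' @export
split_by_patient <- function(patient_ids, test_frac = 0.25) {
  pats <- unique(patient_ids)
  n_test <- max(1L, round(length(pats) * test_frac))
  test_pats <- sample(pats, n_test)
  ifelse(patient_ids %in% test_pats, "test", "train")
}
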
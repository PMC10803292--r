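# Readers and writers for 12-lead ECG records.
#
# Two on-disk formats are supported: a plain CSV fixture format (one file per
# record, a metadata comment line, then one column per lead in mV) and a
# minimal WFDB reader/writer compatible with the PTB-XL records500 layout
# (.hea text header plus a single format-16 interleaved .dat file). Leads are
# always reordered to the canonical order on read.

#' Write a 12-lead ECG record to disk
#'
#' @param record An `ecg_record`.
#' @param path Output path. For `format = "csv"` the file itself; for
#'   `format = "wfdb"` the record stem (the function writes `<path>.hea` and
#'   `<path>.dat`).
#' @param format `"csv"` (full double precision) or `"wfdb"` (format 16,
#'   gain 1000 ADC units per mV, so amplitudes are quantized to 0.001 mV).
#' @return The path, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") write_record_csv(record, path) else write_record_wfdb(record, path)
}

#' Read a 12-lead ECG record
#'
#' Leads are reordered to `ecg_leads()` regardless of on-disk order; the
#' sampling rate is taken from the header. A missing lead is an error naming
#' that lead.
#'
#' @param path File path (CSV) or WFDB record stem (with or without `.hea`).
#' @param format `"csv"` or `"wfdb"`.
#' @return An `ecg_record`.
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

write_record_csv <- function(record, path) {
  meta <- sprintf("#ecglead record_id=%s patient_id=%s age=%s confirmed=%s fs=%s label=%s",
                  record$record_id, record$patient_id, record$age,
                  record$confirmed, record$fs, record$label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  df <- as.data.frame(t(record$signals))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines1 <- readLines(path, n = 1)
  if (!startsWith(lines1, "#ecglead"))
    stop("not an ecglead CSV fixture (missing metadata line): ", path)
  kv <- regmatches(lines1, gregexpr("[A-Za-z_]+=[^ ]+", lines1))[[1]]
  meta <- setNames(sub("^[A-Za-z_]+=", "", kv), sub("=.*$", "", kv))
  df <- read.csv(path, skip = 1, check.names = FALSE)
  missing <- setdiff(ecg_leads(), names(df))
  if (length(missing))
    stop("missing lead(s) in ", path, ": ", paste(missing, collapse = ", "))
  sig <- t(as.matrix(df[, ecg_leads(), drop = FALSE]))
  rownames(sig) <- ecg_leads()
  new_ecg_record(record_id = meta[["record_id"]],
                 patient_id = meta[["patient_id"]],
                 age = as.numeric(meta[["age"]]),
                 confirmed = as.logical(meta[["confirmed"]]),
                 fs = as.numeric(meta[["fs"]]),
                 signals = sig, label = meta[["label"]])
}

# ---- WFDB (PTB-XL records500 layout, format 16) ----------------------------

write_record_wfdb <- function(record, path, gain = 1000) {
  stem <- sub("\\.hea$", "", path)
  base <- basename(stem)
  sig <- record$signals
  n_sig <- nrow(sig); n_samp <- ncol(sig)
  adc <- round(sig * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hdr <- c(sprintf("%s %d %g %d", base, n_sig, record$fs, n_samp),
           sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
                   base, gain, adc[, 1], rownames(sig)),
           sprintf("#age=%s confirmed=%s label=%s patient_id=%s",
                   record$age, record$confirmed, record$label,
                   record$patient_id))
  writeLines(hdr, paste0(stem, ".hea"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  # sample-interleaved: all signals at t=1, then t=2, ...
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(stem)
}

read_record_wfdb <- function(path) {
  stem <- sub("\\.hea$", "", path)
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea)
  comments <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rec_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_fields) < 4) stop("unparseable WFDB header: ", hea)
  n_sig <- as.integer(rec_fields[2])
  fs <- as.numeric(rec_fields[3])
  n_samp <- as.integer(rec_fields[4])
  if (any(is.na(c(n_sig, fs, n_samp)))) stop("unparseable WFDB header: ", hea)
  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_field <- f[3]
    gain <- as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", gain_field))
    baseline <- 0
    bm <- regmatches(gain_field, regexec("\\(([-0-9]+)\\)", gain_field))[[1]]
    if (length(bm) == 2) baseline <- as.numeric(bm[2])
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         name = f[length(f)])
  }
  info <- lapply(sig_lines, parse_sig)
  names_on_disk <- vapply(info, `[[`, "", "name")
  missing <- setdiff(ecg_leads(), names_on_disk)
  if (length(missing))
    stop("missing lead(s) in ", hea, ": ", paste(missing, collapse = ", "))
  dat <- file.path(dirname(hea), info[[1]]$file)
  raw <- readBin(dat, integer(), n = n_sig * n_samp, size = 2,
                 endian = "little")
  adc <- matrix(raw, nrow = n_sig)          # interleaved by sample
  sig <- matrix(0, n_sig, n_samp)
  for (i in seq_len(n_sig))
    sig[i, ] <- (adc[i, ] - info[[i]]$baseline) / info[[i]]$gain
  rownames(sig) <- names_on_disk
  sig <- sig[ecg_leads(), , drop = FALSE]   # canonical order
  meta <- c(age = NA, confirmed = NA, label = "other", patient_id = NA)
  if (length(comments)) {
    kv <- regmatches(comments[1], gregexpr("[A-Za-z_]+=[^ ]+", comments[1]))[[1]]
    got <- setNames(sub("^[A-Za-z_#]+=", "", kv), sub("=.*$", "", kv))
    meta[names(got)] <- got
  }
  new_ecg_record(record_id = basename(stem),
                 patient_id = meta[["patient_id"]],
                 age = suppressWarnings(as.numeric(meta[["age"]])),
                 confirmed = as.logical(meta[["confirmed"]]),
                 fs = fs, signals = sig, label = meta[["label"]])
}

# ---- label mapping ---------------------------------------------------------

#' Map raw diagnostic statements to the six study classes
#'
#' Deterministic mapping from source diagnostic codes (PTB-XL SCP statement
#' style) to `{normal, afib, clbbb, crbbb, lvh, rvh}`. Statements mapping to
#' no class are ignored; a record whose statements map to two or more
#' different classes is a conflict and returns `"other"`, as does a record
#' with no mappable statement. `"other"` records are excluded downstream.
#'
#' @param raw_statements Character vector of statements for one record, or a
#'   list of such vectors for several records.
#' @return A single class string, or a character vector if a list was given.
#' @export
map_labels <- function(raw_statements) {
  if (is.list(raw_statements))
    return(vapply(raw_statements, map_labels, character(1)))
  table <- c(NORM = "normal", SR = "normal",
             AFIB = "afib", AF = "afib",
             CLBBB = "clbbb", LBBB = "clbbb",
             CRBBB = "crbbb", RBBB = "crbbb",
             LVH = "lvh", RVH = "rvh",
             normal = "normal", afib = "afib", clbbb = "clbbb",
             crbbb = "crbbb", lvh = "lvh", rvh = "rvh")
  mapped <- unname(table[toupper(as.character(raw_statements))])
  mapped[is.na(mapped)] <- unname(table[as.character(raw_statements)[is.na(mapped)]])
  mapped <- unique(mapped[!is.na(mapped)])
  if (length(mapped) == 1) mapped else "other"
}

# ---- manifests -------------------------------------------------------------

#' Build a dataset manifest from a list of records
#'
#' @param records List of `ecg_record` objects.
#' @param source One of `"muse-like"`, `"ptbxl"`, `"fixture"`.
#' @return A data.frame with one row per record: `record_id`, `path`,
#'   `patient_id`, `age`, `confirmed`, `fs`, `label`, `source`.
#' @export
cohort_manifest <- function(records, source = "fixture") {
  source <- match.arg(source, c("muse-like", "ptbxl", "fixture"))
  df <- data.frame(
    record_id = vapply(records, `[[`, "", "record_id"),
    path = NA_character_,
    patient_id = vapply(records, `[[`, "", "patient_id"),
    age = vapply(records, function(r) as.numeric(r$age), 0),
    confirmed = vapply(records, function(r) as.logical(r$confirmed), TRUE),
    fs = vapply(records, function(r) as.numeric(r$fs), 0),
    label = vapply(records, `[[`, "", "label"),
    source = source,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$record_id)) stop("duplicate record ids in manifest")
  df
}

#' Write a cohort of records to a directory
#'
#' One file (or WFDB pair) per record plus a `manifest.csv`.
#'
#' @inheritParams write_record
#' @param records List of `ecg_record` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(records, dir, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort_manifest(records)
  ext <- if (format == "csv") ".csv" else ""
  man$path <- file.path(dir, paste0(man$record_id, ext))
  for (i in seq_along(records)) write_record(records[[i]], man$path[i], format)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
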
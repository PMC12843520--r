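#' Write a recording to the internal container
#'
#' Two files: `<path>.json` (subject, channel labels, sampling rate,
#' events, provenance) and `<path>.bin` (little-endian float32, channel
#' major: each channel's samples contiguous). Reading back and rewriting
#' reproduces the files byte for byte.
#'
#' @param recording An [eeg_recording()].
#' @param path Base path without extension.
#' @param provenance Optional list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, provenance = NULL) {
  sidecar <- list(
    format = "neuroforecast-container-v1",
    subject_id = recording$subject_id,
    channels = recording$channels,
    fs = recording$fs,
    n_samples = ncol(recording$data),
    events = recording$events,
    provenance = provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a recording from the internal container
#'
#' @param path Base path without extension (expects `<path>.json` and
#'   `<path>.bin`).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sidecar$format, "neuroforecast-container-v1")) {
    stop("unknown format: ", sidecar$format %||% "<missing>", call. = FALSE)
  }
  events <- as.data.frame(sidecar$events)
  if (!nrow(events)) stop("no video onsets", call. = FALSE)
  sidecar$fs <- as.numeric(sidecar$fs)
  n_ch <- length(sidecar$channels)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = n_ch * sidecar$n_samples, size = 4,
                 endian = "little")
  data <- matrix(raw, nrow = n_ch, byrow = TRUE)
  eeg_recording(sidecar$subject_id, sidecar$channels, sidecar$fs, data, events)
}

#' Write a cleaned epoch to the internal container
#'
#' Stores a [video_epoch()] in the same JSON + float32 container as full
#' recordings, with a single onset event and the epoch's preprocessing
#' provenance (filter edges, thresholds, detected bad channels) in the
#' sidecar.
#'
#' @param epoch A `video_epoch` (typically from [preprocess_recording()]).
#' @param path Base path without extension.
#' @return `path`, invisibly.
#' @export
write_epoch <- function(epoch, path) {
  events <- data.frame(video_id = epoch$video_id,
                       onset_sample = round(epoch$baseline * epoch$fs),
                       duration = epoch_duration(epoch))
  rec <- eeg_recording(epoch$subject_id, epoch$channels, epoch$fs,
                       epoch$data, events)
  prov <- attr(epoch, "provenance") %||% list()
  prov$bad_channels <- epoch$bad_channels
  prov$cleaned <- epoch$cleaned
  prov$baseline <- epoch$baseline
  write_recording(rec, path, provenance = prov)
}

# Canonical 10-20 label: trims whitespace and montage suffixes
# ("EEG Fp1-REF" -> "Fp1"), fixes case, and maps modern temporal names
# (T7/T8/P7/P8) onto the classic T3/T4/T5/T6.
normalize_channel_label <- function(label) {
  x <- trimws(label)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("-(REF|LE|A1|A2|M1|M2)$", "", x, ignore.case = TRUE)
  canon <- c(default_channels(), "T7", "T8", "P7", "P8")
  hit <- match(toupper(x), toupper(canon))
  x[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  swap <- x %in% names(synonyms)
  x[swap] <- synonyms[x[swap]]
  x
}

#' Read a multichannel EEG file (EDF or internal container)
#'
#' Dispatches on extension: `.edf` goes to [read_edf()], anything else is
#' treated as an internal-container base path.
#'
#' @param path File path.
#' @param ... Passed to the format reader.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, ...) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path, ...)
  } else {
    read_recording(sub("\\.(json|bin)$", "", path), ...)
  }
}

trim_ascii <- function(x) sub("\\s+$", "", x)

read_ascii <- function(con, n) trim_ascii(rawToChar(readBin(con, raw(), n)))

pad_ascii <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  paste0(x, strrep(" ", n - nchar(x)))
}

#' Read a 16-bit EDF file
#'
#' Minimal reader for standard EDF (and EDF+ annotation channels): parses
#' the fixed 256-byte header and per-signal headers, decodes the
#' little-endian 16-bit records with the per-signal physical/digital
#' scaling, and extracts video-onset events from an "EDF Annotations"
#' signal when present. All signals must share one sampling rate (the
#' annotation channel excepted).
#'
#' @param path EDF file path.
#' @param subject_id Subject identifier; default: the header's patient
#'   field.
#' @param events Optional events data frame (`video_id`, `onset_sample`,
#'   `duration`) overriding the annotation track.
#' @return An [eeg_recording()] in the file's physical units.
#' @export
read_edf <- function(path, subject_id = NULL, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                                   # version
  patient <- read_ascii(con, 80)
  read_ascii(con, 80); read_ascii(con, 8); read_ascii(con, 8)
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))

  labels <- trim_ascii(vapply(seq_len(ns), function(i) read_ascii(con, 16),
                              character(1)))
  for (i in seq_len(ns)) read_ascii(con, 80)           # transducer
  for (i in seq_len(ns)) read_ascii(con, 8)            # physical dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  for (i in seq_len(ns)) read_ascii(con, 80)           # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), 0L)
  for (i in seq_len(ns)) read_ascii(con, 32)           # reserved
  seek(con, header_bytes)

  is_annot <- labels == "EDF Annotations"
  sig_idx <- which(!is_annot)
  if (any(labels[sig_idx] == "")) {
    stop("unlabeled channel at position ",
         paste(which(labels == "" & !is_annot), collapse = ", "),
         call. = FALSE)
  }
  fs <- nsamp[sig_idx] / record_dur
  if (length(unique(fs)) != 1) {
    stop("signals with mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- fs[1]

  data <- matrix(0, length(sig_idx), n_records * nsamp[sig_idx[1]])
  annot_raw <- raw()
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, integer(), n = nsamp[i], size = 2,
                      endian = "little", signed = TRUE)
      if (is_annot[i]) {
        annot_raw <- c(annot_raw, writeBin(vals, raw(), size = 2,
                                           endian = "little"))
      } else {
        k <- match(i, sig_idx)
        gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
        idx <- ((r - 1) * nsamp[i] + 1):(r * nsamp[i])
        data[k, idx] <- (vals - dmin_[i]) * gain + pmin_[i]
      }
    }
  }
  if (is.null(events)) {
    events <- parse_edf_annotations(annot_raw, fs)
    if (is.null(events) || !nrow(events)) stop("no video onsets", call. = FALSE)
  }
  eeg_recording(subject_id %||% patient,
                normalize_channel_label(labels[sig_idx]), fs, data, events)
}

# Parse EDF+ time-stamped annotation lists into an events data frame.
parse_edf_annotations <- function(bytes, fs) {
  if (!length(bytes)) return(NULL)
  # TAL structure: +onset[\x15duration]\x14label\x14, NUL-separated.
  # (rawToChar rejects embedded NULs, so split the raw vector first.)
  nul <- bytes == as.raw(0)
  if (all(nul)) return(NULL)
  groups <- split(which(!nul), cumsum(nul)[!nul])
  tals <- vapply(groups, function(ix) rawToChar(bytes[ix]), character(1))
  rows <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next   # timekeeping TAL
    od <- strsplit(parts[1], "\x15")[[1]]
    onset <- as.numeric(od[1])
    dur <- if (length(od) > 1) as.numeric(od[2]) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(video_id = parts[2],
                                           onset_sample = round(onset * fs),
                                           duration = dur)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Write a 16-bit EDF file
#'
#' Minimal EDF writer used for interchange and round-trip testing: one
#' 1-second data record per second (the tail beyond the last whole record
#' is dropped), per-channel physical scaling from the data range, and the
#' recording's events stored as EDF+ annotations in an appended
#' "EDF Annotations" signal.
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  n_records <- floor(ncol(recording$data) / fs)
  if (n_records < 1) stop("recording shorter than one record", call. = FALSE)
  n_ch <- length(recording$channels)

  nul <- as.raw(0)
  tals <- lapply(seq_len(nrow(recording$events)), function(k) {
    ev <- recording$events[k, ]
    c(charToRaw(sprintf("+%.6g\x15%.6g\x14%s\x14", ev$onset_sample / fs,
                        ev$duration, ev$video_id)), nul)
  })
  annot_payload <- c(charToRaw("+0\x14\x14"), nul,
                     do.call(c, tals))
  if (length(annot_payload) %% 2) annot_payload <- c(annot_payload, nul)
  annot_nsamp <- length(annot_payload) / 2

  pmin_ <- apply(recording$data, 1, min)
  pmax_ <- apply(recording$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  dmin_ <- -32768; dmax_ <- 32767

  ns <- n_ch + 1L
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wchr <- function(x, n) writeChar(pad_ascii(x, n), con, n, eos = NULL)
  wchr("0", 8); wchr(recording$subject_id, 80); wchr("neuroforecast", 80)
  wchr("01.01.24", 8); wchr("00.00.00", 8)
  wchr(header_bytes, 8); wchr("", 44)
  wchr(n_records, 8); wchr("1", 8); wchr(ns, 4)
  for (ch in recording$channels) wchr(ch, 16)
  wchr("EDF Annotations", 16)
  for (i in seq_len(ns)) wchr("", 80)
  for (i in seq_len(n_ch)) wchr("uV", 8); wchr("", 8)
  for (i in seq_len(n_ch)) wchr(sprintf("%.6g", pmin_[i]), 8); wchr(-1, 8)
  for (i in seq_len(n_ch)) wchr(sprintf("%.6g", pmax_[i]), 8); wchr(1, 8)
  for (i in seq_len(ns)) wchr(dmin_, 8)
  for (i in seq_len(ns)) wchr(dmax_, 8)
  for (i in seq_len(ns)) wchr("", 80)
  for (i in seq_len(n_ch)) wchr(fs, 8); wchr(annot_nsamp, 8)
  for (i in seq_len(ns)) wchr("", 32)

  gains <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(n_ch)) {
      dig <- round((recording$data[i, idx] - pmin_[i]) / gains[i]) + dmin_
      writeBin(as.integer(clamp(dig, dmin_, dmax_)), con, size = 2,
               endian = "little")
    }
    if (r == 1) {
      writeBin(annot_payload, con)
    } else {
      rec_tal <- c(charToRaw(sprintf("+%d\x14\x14", r - 1L)), nul)
      writeBin(c(rec_tal, raw(2 * annot_nsamp - length(rec_tal))), con)
    }
  }
  invisible(path)
}

#' Read and validate the study tables
#'
#' Loads the behavioral/population/outcome/sentiment CSVs, validates
#' ranges, and checks that video ids are consistent across tables.
#' Expected headers: ratings `subject_id, video_id, q1..q5,
#' deal_prediction, dc1..dc14, age, gender`; population `video_id,
#' pop_interest`; outcomes `video_id, deal, amount`; sentiment
#' `video_id` plus covariate columns.
#'
#' @param ratings,population,outcomes Paths to the three required CSVs.
#' @param sentiment Optional sentiment covariate CSV path.
#' @return A `study_tables` list.
#' @export
read_tables <- function(ratings, population, outcomes, sentiment = NULL) {
  rat <- read.csv(ratings, stringsAsFactors = FALSE)
  pop <- read.csv(population, stringsAsFactors = FALSE)
  out <- read.csv(outcomes, stringsAsFactors = FALSE)
  sen <- if (!is.null(sentiment)) read.csv(sentiment, stringsAsFactors = FALSE)

  need <- c("subject_id", "video_id", paste0("q", 1:5), "deal_prediction")
  miss <- setdiff(need, names(rat))
  if (length(miss)) stop("ratings table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  likert <- as.matrix(rat[, paste0("q", 1:5)])
  bad <- which(likert < 1 | likert > 7, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("out-of-range Likert value in ratings row %d (q%d)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  if (!all(out$deal %in% c(0, 1))) stop("deal must be 0/1", call. = FALSE)
  if (any(out$amount < 0)) stop("amount must be >= 0", call. = FALSE)
  if (any(out$deal == 1 & out$amount == 0)) {
    warning("funded video(s) with amount 0: ",
            paste(out$video_id[out$deal == 1 & out$amount == 0],
                  collapse = ", "), call. = FALSE)
  }
  ids <- list(ratings = unique(rat$video_id), population = pop$video_id,
              outcomes = out$video_id)
  if (!is.null(sen)) ids$sentiment <- sen$video_id
  all_ids <- sort(unique(unlist(ids)))
  for (nm in names(ids)[-1]) {
    missing_ids <- setdiff(all_ids, ids[[nm]])
    if (length(missing_ids)) {
      stop("video id mismatch: ", nm, " table is missing ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  message(sprintf("read tables: %d rating rows, %d videos", nrow(rat),
                  length(all_ids)))
  structure(list(ratings = rat, population = pop, outcomes = out,
                 sentiment = sen), class = "study_tables")
}

#' Write study tables to CSV files
#'
#' @param tables A `study_tables` list.
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("ratings", "population", "outcomes", "sentiment")) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
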
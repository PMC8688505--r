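#' Write a recording in the plain matrix + JSON-header fixture format
#'
#' The fixture format keeps everything as text: `<stem>.json` holds the
#' sampling rate, channel labels, positions, reference state and
#' annotations; `<stem>.tsv` holds the samples-by-channels data matrix,
#' tab-separated, no header.
#'
#' @param rec an [eeg_recording].
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
write_eeg_matrix <- function(rec, stem) {
  header <- list(
    fs = rec$fs,
    channels = rec$montage$channel,
    positions = unname(montage_positions(rec$montage)),
    reference = rec$reference,
    annotations = rec$annotations
  )
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(t(rec$data), paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' Read a recording from the matrix + JSON-header fixture format
#'
#' @param stem path without extension, as written by [write_eeg_matrix()].
#' @return An [eeg_recording].
#' @export
read_eeg_matrix <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"),
                                simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t"))
  mont <- montage(header$channels, header$positions)
  ann <- NULL
  if (!is.null(header$annotations) && length(header$annotations)) {
    ann <- tibble::as_tibble(header$annotations)
  }
  eeg_recording(t(x), fs = header$fs, montage = mont,
                reference = header$reference, annotations = ann)
}

#' Write a recording as BrainVision files
#'
#' Writes the standard triplet: `.vhdr` text header, `.vmrk` marker file
#' (annotations become markers), and `.eeg` binary data
#' (IEEE float32, multiplexed, in microvolts).
#'
#' @param rec an [eeg_recording].
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
write_brainvision <- function(rec, stem) {
  base <- basename(stem)
  n_ch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$montage$channel)
  )
  writeLines(hdr, paste0(stem, ".vhdr"))
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(rec$annotations) > 0) {
    a <- rec$annotations
    mrk <- c(mrk, sprintf(
      "Mk%d=Stimulus,%s,%d,%d,0",
      seq_len(nrow(a)) + 1L,
      paste0(a$condition, "/r", a$run),
      as.integer(round(a$onset * rec$fs)) + 1L,
      as.integer(round(a$duration * rec$fs))))
  }
  writeLines(mrk, paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(stem)
}

# minimal INI-section parser for BrainVision headers
parse_vhdr_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && nzchar(section)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      out[[section]][[trimws(kv[1L])]] <-
        trimws(paste(kv[-1L], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports binary multiplexed data in IEEE float32 or int16 (with
#' per-channel resolution), reading markers from the `.vmrk` file into
#' annotations. Channel positions are taken from the built-in 10-10
#' montage where the labels match; unknown labels get placeholder
#' positions on the equator.
#'
#' @param vhdr path to the `.vhdr` header.
#' @return An [eeg_recording].
#' @export
read_brainvision <- function(vhdr) {
  ini <- parse_vhdr_ini(readLines(vhdr, warn = FALSE))
  ci <- ini[["Common Infos"]]
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  if (!is.null(ci$DataOrientation) &&
      toupper(ci$DataOrientation) != "MULTIPLEXED") {
    stop_microdyn("only MULTIPLEXED BrainVision data supported")
  }
  fmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chn <- ini[["Channel Infos"]]
  labels <- character(n_ch)
  resolution <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    parts <- strsplit(chn[[paste0("Ch", i)]], ",", fixed = TRUE)[[1L]]
    labels[i] <- parts[1L]
    if (length(parts) >= 3L && nzchar(parts[3L])) {
      resolution[i] <- as.numeric(parts[3L])
    }
  }
  datafile <- file.path(dirname(vhdr), ci$DataFile)
  sz <- file.info(datafile)$size
  if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(datafile, "numeric", n = sz / 4L, size = 4L,
                    endian = "little")
  } else if (fmt == "INT_16") {
    vals <- readBin(datafile, "integer", n = sz / 2L, size = 2L,
                    signed = TRUE, endian = "little")
  } else {
    stop_microdyn("unsupported BinaryFormat '%s'", fmt)
  }
  n_samp <- length(vals) %/% n_ch
  x <- matrix(vals[seq_len(n_samp * n_ch)], nrow = n_ch)
  x <- x * resolution
  mont <- montage_for_labels(labels)
  ann <- NULL
  vmrk <- file.path(dirname(vhdr), ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(vmrk)) {
    mi <- parse_vhdr_ini(readLines(vmrk, warn = FALSE))[["Marker Infos"]]
    rows <- list()
    for (nm in names(mi)) {
      parts <- strsplit(mi[[nm]], ",", fixed = TRUE)[[1L]]
      if (length(parts) < 4L || parts[1L] == "New Segment") next
      desc <- strsplit(parts[2L], "/r", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        onset = (as.numeric(parts[3L]) - 1) / fs,
        duration = as.numeric(parts[4L]) / fs,
        condition = desc[1L],
        run = if (length(desc) > 1L) as.integer(desc[2L]) else NA_integer_)
    }
    if (length(rows)) ann <- dplyr::bind_rows(rows)
  }
  eeg_recording(x, fs = fs, montage = mont, annotations = ann)
}

# montage for an arbitrary label set: known 10-10 labels get their built-in
# positions, unknown ones placeholder positions spread on the equator
montage_for_labels <- function(labels) {
  ref <- montage_1010()
  pos <- matrix(NA_real_, length(labels), 3L)
  hit <- match(labels, ref$channel)
  pos[!is.na(hit), ] <- montage_positions(ref)[hit[!is.na(hit)], ]
  missing <- which(is.na(hit))
  if (length(missing)) {
    ang <- seq(0, 2 * pi, length.out = length(missing) + 1L)[-1L] + 0.1
    pos[missing, ] <- cbind(cos(ang), sin(ang), 0)
  }
  montage(labels, pos)
}

#' Read an EDF recording
#'
#' Minimal reader for continuous European Data Format files: parses the
#' fixed-width text header, reads the 16-bit little-endian data records,
#' and rescales to physical units per channel. Annotation channels
#' ("EDF Annotations") are dropped.
#'
#' @param path path to the `.edf` file.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd(8L)
  rd(80L); rd(80L); rd(8L); rd(8L)        # patient, recording, date, time
  header_bytes <- as.integer(rd(8L))
  rd(44L)                                  # reserved
  n_records <- as.integer(rd(8L))
  record_s <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1L))
  labels <- fld(16L)
  fld(80L)                                 # transducer
  fld(8L)                                  # physical dimension
  phys_min <- as.numeric(fld(8L))
  phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L))
  dig_max <- as.numeric(fld(8L))
  fld(80L)                                 # prefiltering
  spr <- as.integer(fld(8L))               # samples per record
  fld(32L)                                 # reserved
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (length(unique(spr[keep])) != 1L) {
    stop_microdyn("channels with mixed sampling rates not supported")
  }
  fs <- spr[keep][1L] / record_s
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  chunks <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    rec <- matrix(NA_real_, sum(keep), spr[keep][1L])
    ki <- 0L
    for (ch in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                   endian = "little")
      if (keep[ch]) {
        ki <- ki + 1L
        rec[ki, ] <- v * gain[ch] + offset[ch]
      }
    }
    chunks[[r]] <- rec
  }
  x <- do.call(cbind, chunks)
  mont <- montage_for_labels(sub("^EEG ", "", labels[keep]))
  eeg_recording(x, fs = fs, montage = mont)
}

#' Write a label sequence as one-label-per-line text
#'
#' @param seq a [label_sequence].
#' @param path output file; the first line is a JSON header with `fs` and
#'   `n_classes`, subsequent lines are the labels.
#' @return `path`, invisibly.
#' @export
write_label_sequence <- function(seq, path) {
  hdr <- jsonlite::toJSON(list(fs = seq_fs(seq),
                               n_classes = seq_classes(seq)),
                          auto_unbox = TRUE)
  writeLines(c(paste0("#", hdr), as.character(as.integer(seq))), path)
  invisible(path)
}

#' Read a label sequence written by [write_label_sequence()]
#'
#' @param path input file.
#' @return A [label_sequence].
#' @export
read_label_sequence <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  label_sequence(as.integer(lines[-1L]), fs = hdr$fs,
                 n_classes = hdr$n_classes)
}

#' Save / load a microstate model as JSON
#'
#' @param model a [microstate_model].
#' @param path JSON file path.
#' @return `path` invisibly, or the model.
#' @export
write_microstate_model <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, channels = colnames(model$maps),
         maps = unname(model$maps), cost = model$cost, cv = model$cv,
         gev = model$gev, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_microstate_model
#' @export
read_microstate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  microstate_model(obj$maps, channel_labels = obj$channels,
                   cost = obj$cost %||% NA_real_, cv = obj$cv %||% NA_real_,
                   gev = obj$gev %||% NA_real_,
                   seed = obj$seed %||% NA_integer_)
}
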
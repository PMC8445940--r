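# Minimal EDF (European Data Format) support: continuous 16-bit recordings
# only, which covers standard rodent ECoG exports. Physical-unit scaling is
# applied on read; EDF+ annotations/discontinuous files are out of scope.

read_edf_header <- function(con) {
  rd <- function(nchars) {
    trimws(rawToChar(readBin(con, "raw", n = nchars)))
  }
  version <- rd(8)
  patient <- rd(80)
  recording <- rd(80)
  startdate <- rd(8)
  starttime <- rd(8)
  n_header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  n_signals <- as.integer(rd(4))
  if (is.na(n_signals) || n_signals < 1L) {
    stop("not a valid EDF file (bad signal count)", call. = FALSE)
  }
  per <- function(nchars) vapply(seq_len(n_signals), function(i) rd(nchars), "")
  list(
    version = version, patient = patient, recording = recording,
    startdate = startdate, starttime = starttime,
    n_header_bytes = n_header_bytes, reserved = reserved,
    n_records = n_records, record_dur = record_dur, n_signals = n_signals,
    labels = per(16), transducer = per(80), phys_dim = per(8),
    phys_min = as.numeric(per(8)), phys_max = as.numeric(per(8)),
    dig_min = as.numeric(per(8)), dig_max = as.numeric(per(8)),
    prefilter = per(80), samples_per_record = as.integer(per(8)),
    sig_reserved = per(32)
  )
}

read_edf_channel <- function(path, channel = NULL, fs_override = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  labels <- hdr$labels
  if (is.null(channel)) {
    if (hdr$n_signals > 1L) {
      stop("EDF has ", hdr$n_signals, " channels (",
           paste(labels, collapse = ", "), "); specify `channel`",
           call. = FALSE)
    }
    idx <- 1L
  } else {
    idx <- match(channel, labels)
    if (is.na(idx)) {
      stop("channel '", channel, "' not found in EDF (available: ",
           paste(labels, collapse = ", "), ")", call. = FALSE)
    }
  }
  spr <- hdr$samples_per_record
  nrec <- hdr$n_records
  # whole data block at once, then de-interleave the requested signal
  raw_all <- readBin(con, "integer", n = sum(spr) * nrec, size = 2,
                     signed = TRUE, endian = "little")
  offsets <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  take <- as.vector(outer(offsets[idx] + seq_len(spr[idx]),
                          (seq_len(nrec) - 1L) * per_rec, `+`))
  digital <- raw_all[take]
  gain <- (hdr$phys_max[idx] - hdr$phys_min[idx]) /
    (hdr$dig_max[idx] - hdr$dig_min[idx])
  physical <- (digital - hdr$dig_min[idx]) * gain + hdr$phys_min[idx]
  fs <- if (!is.null(fs_override)) fs_override else spr[idx] / hdr$record_dur
  ecog_ts(physical, fs = fs, channel = labels[idx])
}

# Internal EDF writer used to build test fixtures in code (keeps the repo
# free of binary files). One or more channels, common record duration.
write_edf_minimal <- function(path, signals, fs, record_dur = 1,
                              phys_range = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1L, !is.null(names(signals)))
  ns <- length(signals)
  spr <- as.integer(round(fs * record_dur))
  nlen <- unique(vapply(signals, length, 1L))
  stopifnot(length(nlen) == 1L, nlen %% spr == 0L)
  nrec <- nlen %/% spr
  if (is.null(phys_range)) {
    amax <- max(1e-6, vapply(signals, function(x) max(abs(x)), 1))
    phys_range <- c(-amax, amax)
  }
  dmin <- -32768; dmax <- 32767
  gain <- (phys_range[2] - phys_range[1]) / (dmax - dmin)
  pad <- function(x, w) {
    s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, w)
    sprintf("%-*s", w, s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8)); wr(pad("X", 80)); wr(pad("X", 80))
  wr(pad("01.01.26", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + ns), 8)); wr(pad("", 44))
  wr(pad(nrec, 8)); wr(pad(record_dur, 8)); wr(pad(ns, 4))
  for (nm in names(signals)) wr(pad(nm, 16))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad("uV", 8))
  for (i in seq_len(ns)) wr(pad(signif(phys_range[1], 7), 8))
  for (i in seq_len(ns)) wr(pad(signif(phys_range[2], 7), 8))
  for (i in seq_len(ns)) wr(pad(dmin, 8))
  for (i in seq_len(ns)) wr(pad(dmax, 8))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(spr, 8))
  for (i in seq_len(ns)) wr(pad("", 32))
  for (r in seq_len(nrec)) {
    for (nm in names(signals)) {
      chunk <- signals[[nm]][((r - 1) * spr + 1):(r * spr)]
      digital <- as.integer(pmin(pmax(
        round((chunk - phys_range[1]) / gain + dmin), dmin), dmax))
      writeBin(digital, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
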
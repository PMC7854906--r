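# File interfaces: a minimal EDF (European Data Format) reader/writer
# for continuous recordings (no installed R package provides one), RDS
# persistence for pipeline objects, and YAML round-tripping for
# configurations.

.pad <- function(s, n) formatC(substr(s, 1, n), width = -n)

#' Read a continuous EDF recording
#'
#' Supports plain continuous EDF with identical sampling across data
#' records; annotations channels are not supported. Digital values are
#' rescaled to physical units using the per-signal calibration fields.
#'
#' @param path EDF file path.
#' @return List with `signal` (`[n_channels, n_samples]`), `fs` and
#'   `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_records <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1) stop("not a valid EDF header")
  field <- function(width) {
    raw <- readChar(con, width * ns, useBytes = TRUE)
    vapply(seq_len(ns), function(i)
      trimws(substr(raw, (i - 1) * width + 1, i * width)), character(1))
  }
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_records * spr[1])
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    block <- matrix(block, nrow = spr[1])
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    sig[, cols] <- t(block)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- sig * scale + (pmin - dmin * scale)
  rownames(sig) <- labels
  list(signal = sig, fs = fs, channel_names = labels)
}

#' Write a continuous EDF recording
#'
#' One-second data records, 16-bit samples scaled to each channel's
#' range. The signal is truncated to a whole number of records.
#'
#' @param path output path.
#' @param signal numeric matrix `[n_channels, n_samples]`.
#' @param fs sampling rate in Hz (must be a whole number).
#' @param channel_names one label per channel; defaults to rownames.
#' @export
write_edf <- function(path, signal, fs, channel_names = rownames(signal)) {
  signal <- as.matrix(signal)
  if (abs(fs - round(fs)) > 1e-9) stop("fs must be a whole number for EDF")
  fs <- as.integer(round(fs))
  ns <- nrow(signal)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ns))
  n_records <- ncol(signal) %/% fs
  if (n_records < 1) stop("signal shorter than one 1-s record")
  signal <- signal[, seq_len(n_records * fs), drop = FALSE]
  pmin <- apply(signal, 1, min); pmax <- apply(signal, 1, max)
  same <- pmax - pmin < 1e-12
  pmax[same] <- pmin[same] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((signal - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(.pad(s, n), con, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8); wr("", 44)
  wr(as.character(n_records), 8); wr("1", 8); wr(as.character(ns), 4)
  for (s in channel_names) wr(s, 16)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr("uV", 8)
  for (v in pmin) wr(sprintf("%.6g", v), 8)
  for (v in pmax) wr(sprintf("%.6g", v), 8)
  for (s in seq_len(ns)) wr(as.character(dmin), 8)
  for (s in seq_len(ns)) wr(as.character(dmax), 8)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(as.character(fs), 8)
  for (s in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Save / load pipeline objects
#'
#' Thin RDS wrappers used as the array container for epoched sets,
#' feature stacks, image stacks and trained models.
#'
#' @param x object to save.
#' @param path file path.
#' @return `read_dataset` returns the stored object.
#' @export
write_dataset <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) readRDS(path)

#' Read / write an adaptation configuration as YAML
#'
#' @param path YAML file path.
#' @param config an [adaptation_config()].
#' @return `read_config` returns an [adaptation_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(adaptation_config,
          vals[intersect(names(vals), names(formals(adaptation_config)))])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  drop <- c("batch_total")
  yaml::write_yaml(config[setdiff(names(config), drop)], path)
  invisible(path)
}
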
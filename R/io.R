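#' Export multi-trial sensor data to TSV
#'
#' Plain-text interchange for trials-by-time-by-channel arrays: three
#' `#`-prefixed header lines (format tag, `J`/`T`/`M`, sampling rate)
#' followed by `J * T` rows of `M` channel values (trial-major order).
#'
#' @param trials `J x T x M` array (or `T x M` matrix).
#' @param path output path.
#' @param sfreq sampling rate in Hz (metadata only).
#' @export
write_meg_tsv <- function(trials, path, sfreq = NA_real_) {
  if (is.matrix(trials)) trials <- array(trials, c(1, dim(trials)))
  J <- dim(trials)[1]; T <- dim(trials)[2]; M <- dim(trials)[3]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# megjoint meg v1",
               paste0("# dims\t", J, "\t", T, "\t", M),
               paste0("# sfreq\t", sfreq)), con)
  flat <- matrix(0, J * T, M)
  for (j in seq_len(J)) flat[(j - 1) * T + seq_len(T), ] <- trials[j, , ]
  write.table(format(flat, digits = 17), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import multi-trial sensor data from TSV
#'
#' @param path file written by [write_meg_tsv()].
#' @return list with `trials` (`J x T x M` array) and `sfreq`.
#' @export
read_meg_tsv <- function(path) {
  hdr <- readLines(path, n = 3)
  if (!startsWith(hdr[1], "#")) stop("missing header in ", path)
  dims <- as.integer(strsplit(hdr[2], "\t")[[1]][-1])
  sfreq <- suppressWarnings(as.numeric(strsplit(hdr[3], "\t")[[1]][2]))
  J <- dims[1]; T <- dims[2]; M <- dims[3]
  tab <- as.matrix(read.table(path, skip = 3, sep = "\t"))
  if (nrow(tab) != J * T || ncol(tab) != M) stop("data shape mismatch")
  trials <- array(0, c(J, T, M))
  for (j in seq_len(J)) trials[j, , ] <- tab[(j - 1) * T + seq_len(T), ]
  list(trials = trials, sfreq = sfreq)
}
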
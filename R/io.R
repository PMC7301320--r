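#' Write an epoch set as a long-format table
#'
#' Serializes epochs to the canonical long-format CSV: one row per
#' subject, drug, block, condition, trial, channel and time point, with
#' amplitudes in microvolts (column `amplitude_uv`).
#'
#' @param epochs an `epoch_set`.
#' @param file output CSV path.
#' @param subject,drug identifiers stored with every row.
#' @return the file path, invisibly.
#' @export
write_epoch_table <- function(epochs, file, subject = 1, drug = "placebo") {
  d <- dim(epochs$data)
  info <- epochs$info
  long <- data.frame(
    subject = subject, drug = drug,
    block = rep(info$block %||% 1L, each = d[2] * d[3]),
    condition = rep(info$condition, each = d[2] * d[3]),
    trial = rep(info$trial, each = d[2] * d[3]),
    channel = rep(rep(epochs$channels, each = d[3]), d[1]),
    time_ms = rep(epochs$times_ms, d[1] * d[2]),
    amplitude_uv = as.vector(aperm(epochs$data, c(3, 2, 1))),
    stringsAsFactors = FALSE)
  utils::write.csv(long, file, row.names = FALSE)
  invisible(file)
}

#' Read a long-format epoch table
#'
#' Inverse of [write_epoch_table()]. Channel names are checked against
#' the montage and amplitudes must be in microvolts (`amplitude_uv`); a
#' table with an `amplitude_mv` column (or other unit suffix) is
#' rejected, as are malformed rows, with their row numbers.
#'
#' @param file CSV path.
#' @param montage an `erp_montage`.
#' @param sfreq sampling rate in Hz of the stored epochs (default 512).
#' @return an `epoch_set`; `subject` and `drug` are carried in `$info`.
#' @export
read_epoch_table <- function(file, montage = gonogo_montage(), sfreq = 512) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject", "drug", "block", "condition", "trial", "channel",
            "time_ms", "amplitude_uv")
  if (!("amplitude_uv" %in% names(tab))) {
    other <- grep("^amplitude_", names(tab), value = TRUE)
    if (length(other)) {
      stop_input("amplitude must be in microvolts (found %s)",
                 paste(other, collapse = ", "))
    }
  }
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_input("missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$amplitude_uv) | !is.finite(tab$time_ms))
  if (length(bad)) {
    stop_input("malformed rows: %s", paste(utils::head(bad, 10), collapse = ", "))
  }
  unknown <- setdiff(unique(tab$channel), montage$channel)
  if (length(unknown)) {
    rows <- which(tab$channel %in% unknown)
    stop_input("unknown channel(s) %s (rows %s)",
               paste(unknown, collapse = ", "),
               paste(utils::head(rows, 10), collapse = ", "))
  }
  times <- sort(unique(tab$time_ms))
  channels <- unique(tab$channel)
  key <- unique(tab[, c("subject", "drug", "block", "condition", "trial")])
  key <- key[order(key$subject, key$drug, key$block, key$trial), ]
  arr <- array(NA_real_, dim = c(nrow(key), length(channels), length(times)),
               dimnames = list(NULL, channels, NULL))
  tab$.epoch <- match(interaction(tab$subject, tab$drug, tab$block, tab$trial,
                                  drop = TRUE),
                      interaction(key$subject, key$drug, key$block, key$trial,
                                  drop = TRUE))
  arr[cbind(tab$.epoch, match(tab$channel, channels),
            match(tab$time_ms, times))] <- tab$amplitude_uv
  if (anyNA(arr)) stop_input("incomplete epochs: not every channel x time present")
  info <- key
  rownames(info) <- NULL
  new_epoch_set(arr, channels, channels %in% scalp_channels(montage),
                times, sfreq, info)
}
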
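#' Write a trial set to the long-format CSV interchange file
#'
#' One row per (trial, channel): columns `subject, trial, label, channel,
#' t0 ... t<n-1>` where `t<k>` is the sample at time `k / fs` in microvolts.
#' The sampling rate is recorded in a `# fs=<Hz>` comment line above the
#' header so the file round-trips without external metadata.
#'
#' @param ts A `trialset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trialset_csv <- function(ts, path) {
  n_samp <- ncol(ts$trials[[1]])
  n_ch <- nrow(ts$trials[[1]])
  rows <- vector("list", length(ts$trials))
  for (i in seq_along(ts$trials)) {
    m <- ts$trials[[i]]
    rows[[i]] <- data.frame(subject = ts$subject_id, trial = i,
                            label = as.character(ts$labels[i]),
                            channel = ts$channel_names,
                            m, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  names(df)[-(1:4)] <- paste0("t", seq_len(n_samp) - 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", ts$fs), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trial set from the long-format CSV interchange file
#'
#' @param path File written by [write_trialset_csv()] (or any file matching
#'   the documented format).
#' @param fs Sampling rate override; taken from the `# fs=` comment line
#'   when present.
#' @return A `trialset`.
#' @export
read_trialset_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^# fs=", first)) {
    fs <- fs %||% as.numeric(sub("^# fs=", "", first))
  }
  if (is.null(fs))
    stop_afcsp("sampling rate not recorded in file and not supplied",
               class = "afcsp_parse_error")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject", "trial", "label", "channel")
  if (!all(need %in% names(df)))
    stop_afcsp("trial CSV missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "),
               class = "afcsp_parse_error")
  samp_cols <- grep("^t[0-9]+$", names(df), value = TRUE)
  samp_cols <- samp_cols[order(as.integer(sub("^t", "", samp_cols)))]
  trial_ids <- sort(unique(df$trial))
  channel_names <- df$channel[df$trial == trial_ids[1]]
  trials <- vector("list", length(trial_ids))
  labels <- character(length(trial_ids))
  for (k in seq_along(trial_ids)) {
    sub <- df[df$trial == trial_ids[k], , drop = FALSE]
    if (!identical(sub$channel, channel_names))
      stop_afcsp("trial ", trial_ids[k],
                 ": channel set or order differs from first trial",
                 class = "afcsp_parse_error")
    lab <- unique(sub$label)
    if (length(lab) != 1)
      stop_afcsp("trial ", trial_ids[k], ": inconsistent labels",
                 class = "afcsp_parse_error")
    labels[k] <- lab
    m <- as.matrix(sub[, samp_cols, drop = FALSE])
    dimnames(m) <- list(channel_names, NULL)
    trials[[k]] <- m
  }
  std <- c("flexion", "extension", "abduction")
  trialset(trials, labels, channel_names, fs,
           subject_id = as.character(df$subject[1]),
           class_labels = if (all(labels %in% std)) std else unique(labels))
}
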
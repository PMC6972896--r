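#' Write session records as CSV files
#'
#' One UTF-8 CSV per session. Header comment lines (prefixed \code{#}) carry
#' subject, condition, session index and warm-up convention; data columns
#' are trial_index (1-based, contiguous), location, rewarded, valid.
#'
#' @param records a [session_record()] or list of them.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_sessions <- function(records, dir) {
  if (inherits(records, "session_record")) records <- list(records)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(records, function(r) {
    stopifnot(inherits(r, "session_record"))
    path <- file.path(dir, sprintf("%s_%s%02d.csv", r$subject_id,
                                   r$condition, r$session_index))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(sprintf("# subject_id: %s", r$subject_id),
                 sprintf("# condition: %s", r$condition),
                 sprintf("# session_index: %d", r$session_index),
                 sprintf("# warmup: %s", r$warmup)), con)
    write.csv(data.frame(trial_index = seq_along(r$locations),
                         location = unclass(r$locations),
                         rewarded = r$rewarded, valid = r$valid),
              con, row.names = FALSE, quote = FALSE)
    path
  }, character(1))
  invisible(paths)
}

read_one_session <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty session file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(subject_id = "S1", condition = NA_character_,
               session_index = 1L, warmup = "reward_all")
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.+)$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("malformed session file (no data rows): ", path)
  df <- tryCatch(
    read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("malformed session file ", path, ": ",
                             conditionMessage(e)))
  need <- c("trial_index", "location", "rewarded")
  if (!all(need %in% names(df)))
    stop("malformed session file ", path, ": missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.na(meta$condition)) stop("missing condition header in ", path)
  if (!meta$condition %in% c("training", "complexity", "p75"))
    stop("unknown condition '", meta$condition, "' in ", path)
  if (any(df$trial_index != seq_len(nrow(df)))) {
    bad <- which(df$trial_index != seq_len(nrow(df)))[1]
    stop("trial_index not contiguous at row ", bad, " of ", path)
  }
  rep_at <- which(df$location[-1] == df$location[-nrow(df)])
  if (length(rep_at))
    stop("consecutive repeat at row ", rep_at[1] + 1L, " of ", path)
  session_record(df$location, df$rewarded, condition = meta$condition,
                 subject_id = meta$subject_id,
                 session_index = as.integer(meta$session_index),
                 valid = if ("valid" %in% names(df)) df$valid else NULL,
                 warmup = meta$warmup)
}

#' Read session records from CSV
#'
#' Reads one session file, or every \code{*.csv} session file in a
#' directory. Validation errors (repeated locations, trial-index gaps,
#' unknown condition, malformed files) name the offending row and file.
#'
#' @param path a session CSV file or a directory of them.
#' @return a list of [session_record()]s.
#' @export
read_sessions <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) stop("no session files in ", path)
    return(lapply(files, read_one_session))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  list(read_one_session(path))
}
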
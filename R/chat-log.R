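# Canonical chat event-log data model and its CSV dialect.

CHANNEL_LEVELS <- c("web", "whatsapp", "messenger", "wechat", "sms")
USER_TYPE_LEVELS <- c("nonrepeat", "repeat")
RISK_LEVELS <- c("low", "medium", "high_crisis")

LOG_COLUMNS <- c(
  "user_id", "channel", "arrival_ts", "tos_accepted", "user_type",
  "pickup_ts", "end_ts", "renege_ts", "risk_level", "counselor_id"
)
TS_COLUMNS <- c("arrival_ts", "pickup_ts", "end_ts", "renege_ts")

#' Construct a chat event log
#'
#' A chat log is a data frame with one row per chat request, tracking the
#' full lifecycle: arrival, terms-of-service (TOS) decision, queueing, and
#' either service (pickup/end) or abandonment (renege). Timestamps are
#' `POSIXct` at one-second resolution; absent lifecycle stages are `NA`.
#'
#' @param user_id character; opaque user identifier.
#' @param channel one of `"web"`, `"whatsapp"`, `"messenger"`, `"wechat"`,
#'   `"sms"`.
#' @param arrival_ts,pickup_ts,end_ts,renege_ts `POSIXct` timestamps;
#'   `pickup_ts`/`end_ts`/`renege_ts` may be `NA`.
#' @param tos_accepted logical; did the visitor accept the terms of service?
#' @param user_type `"nonrepeat"` or `"repeat"` (`NA` when TOS rejected).
#' @param risk_level counselor-rated risk: `"low"`, `"medium"`,
#'   `"high_crisis"`, or `NA`.
#' @param counselor_id character or `NA`.
#' @param validate check the lifecycle invariants (default `TRUE`).
#' @return A data frame of class `chat_log`.
#' @export
chat_log <- function(user_id = character(), channel = character(),
                     arrival_ts = as.POSIXct(character(), tz = "UTC"),
                     tos_accepted = logical(), user_type = NA_character_,
                     pickup_ts = NA, end_ts = NA, renege_ts = NA,
                     risk_level = NA_character_, counselor_id = NA_character_,
                     validate = TRUE) {
  n <- length(user_id)
  rec <- function(x) {
    if (length(x) == n) x else if (length(x) == 1) rep(x, n) else if (n == 0) x[0] else
      stop_domain("chat_log column of length ", length(x), " cannot fill ", n, " rows")
  }
  as_ts <- function(x) {
    x <- rec(x)
    if (inherits(x, "POSIXct")) x else as.POSIXct(as.numeric(x), origin = SIM_ORIGIN, tz = "UTC")
  }
  log <- data.frame(
    user_id = as.character(user_id),
    channel = as.character(rec(channel)),
    arrival_ts = as_ts(arrival_ts),
    tos_accepted = as.logical(rec(tos_accepted)),
    user_type = as.character(rec(user_type)),
    pickup_ts = as_ts(pickup_ts),
    end_ts = as_ts(end_ts),
    renege_ts = as_ts(renege_ts),
    risk_level = as.character(rec(risk_level)),
    counselor_id = as.character(rec(counselor_id)),
    stringsAsFactors = FALSE
  )
  class(log) <- c("chat_log", "data.frame")
  if (validate) validate_chat_log(log)
  log
}

#' Validate chat-log lifecycle invariants
#'
#' Checks enum domains, timestamp ordering (`arrival <= pickup <= end`),
#' the zombie rule (a renege may only coexist with a *later* pickup), and
#' that TOS-rejected rows carry no downstream lifecycle fields.
#'
#' @param log a `chat_log` data frame.
#' @return `log`, invisibly; errors name the offending row and column.
#' @export
validate_chat_log <- function(log) {
  fail <- function(row, col, msg) {
    stop_domain(sprintf("invalid chat log (row %d, column %s): %s", row, col, msg))
  }
  bad <- which(!log$channel %in% CHANNEL_LEVELS)
  if (length(bad)) fail(bad[1], "channel", paste("unknown value", log$channel[bad[1]]))
  bad <- which(!is.na(log$user_type) & !log$user_type %in% USER_TYPE_LEVELS)
  if (length(bad)) fail(bad[1], "user_type", paste("unknown value", log$user_type[bad[1]]))
  bad <- which(!is.na(log$risk_level) & !log$risk_level %in% RISK_LEVELS)
  if (length(bad)) fail(bad[1], "risk_level", paste("unknown value", log$risk_level[bad[1]]))
  bad <- which(is.na(log$arrival_ts))
  if (length(bad)) fail(bad[1], "arrival_ts", "missing arrival timestamp")
  bad <- which(is.na(log$tos_accepted))
  if (length(bad)) fail(bad[1], "tos_accepted", "missing TOS decision")

  bad <- which(!is.na(log$pickup_ts) & log$pickup_ts < log$arrival_ts)
  if (length(bad)) fail(bad[1], "pickup_ts", "pickup precedes arrival")
  bad <- which(!is.na(log$pickup_ts) & !is.na(log$end_ts) & log$end_ts < log$pickup_ts)
  if (length(bad)) fail(bad[1], "end_ts", "chat end precedes pickup")
  bad <- which(!is.na(log$renege_ts) & !is.na(log$pickup_ts) &
                 log$pickup_ts <= log$renege_ts)
  if (length(bad)) {
    fail(bad[1], "renege_ts",
         "renege may only coexist with a later (zombie) pickup")
  }
  rejected <- !log$tos_accepted
  bad <- which(rejected & (!is.na(log$pickup_ts) | !is.na(log$renege_ts) |
                             !is.na(log$risk_level)))
  if (length(bad)) {
    fail(bad[1], "tos_accepted",
         "TOS-rejected request carries pickup/renege/risk fields")
  }
  invisible(log)
}

#' Write a chat log to CSV
#'
#' The on-disk dialect has a fixed header
#' (`user_id,channel,arrival_ts,tos_accepted,user_type,pickup_ts,end_ts,renege_ts,risk_level,counselor_id`),
#' ISO-8601 UTC timestamps (`2020-11-01T00:00:00Z`), lowercase
#' `true`/`false` booleans, and empty cells for absent fields.
#'
#' @param log a `chat_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chat_log <- function(log, path) {
  validate_chat_log(log)
  out <- as.data.frame(log)[LOG_COLUMNS]
  for (col in TS_COLUMNS) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  }
  out$tos_accepted <- ifelse(out$tos_accepted, "true", "false")
  for (col in c("user_type", "risk_level", "counselor_id")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a chat log from CSV
#'
#' Inverse of [write_chat_log()]: `read_chat_log(write_chat_log(x))` is the
#' identity on valid logs. Malformed timestamps or unknown enum values raise
#' a parse error naming the row and column.
#'
#' @param path CSV file path.
#' @return A validated `chat_log`.
#' @export
read_chat_log <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(LOG_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop_domain("chat log CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  parse_ts <- function(x, col) {
    out <- as.POSIXct(rep(NA_real_, length(x)), origin = SIM_ORIGIN, tz = "UTC")
    present <- !is.na(x) & nzchar(x)
    parsed <- as.POSIXct(x[present], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    if (anyNA(parsed)) {
      row <- which(present)[which(is.na(parsed))[1]]
      stop_domain(sprintf("parse error (row %d, column %s): malformed timestamp '%s'",
                          row, col, x[row]))
    }
    out[present] <- parsed
    out
  }
  blank_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  tos <- tolower(raw$tos_accepted)
  bad <- which(!tos %in% c("true", "false"))
  if (length(bad)) {
    stop_domain(sprintf("parse error (row %d, column tos_accepted): expected true/false, got '%s'",
                        bad[1], raw$tos_accepted[bad[1]]))
  }
  chat_log(
    user_id = raw$user_id,
    channel = raw$channel,
    arrival_ts = parse_ts(raw$arrival_ts, "arrival_ts"),
    tos_accepted = tos == "true",
    user_type = blank_na(raw$user_type),
    pickup_ts = parse_ts(raw$pickup_ts, "pickup_ts"),
    end_ts = parse_ts(raw$end_ts, "end_ts"),
    renege_ts = parse_ts(raw$renege_ts, "renege_ts"),
    risk_level = blank_na(raw$risk_level),
    counselor_id = blank_na(raw$counselor_id)
  )
}

# Lifecycle times in fractional minutes relative to an origin; the working
# unit for all queueing arithmetic.
log_minutes <- function(log, origin = SIM_ORIGIN) {
  data.frame(
    arrival = ts_to_minutes(log$arrival_ts, origin),
    pickup = ts_to_minutes(log$pickup_ts, origin),
    end = ts_to_minutes(log$end_ts, origin),
    renege = ts_to_minutes(log$renege_ts, origin)
  )
}
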
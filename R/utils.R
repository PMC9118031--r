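# Internal helpers shared across modules.

# The study area (south-central Sweden) uses a fixed UTC+1 civil time with no
# DST adjustment; all timestamps in the package are interpreted in this zone.
# Note the Etc/GMT sign convention: "Etc/GMT-1" is UTC+1.
BR_TZ <- "Etc/GMT-1"

#' Time zone used for all timestamps
#'
#' All biologging timestamps are handled in a fixed UTC+1 civil time
#' (study-area local time without daylight-saving adjustment).
#'
#' @return The Olson name of the package time zone, `"Etc/GMT-1"`.
#' @export
br_timezone <- function() BR_TZ

# Coerce to POSIXct in the package time zone.
as_br_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- BR_TZ
    return(x)
  }
  as.POSIXct(x, tz = BR_TZ)
}

# Civil date (in the package time zone) of an instant.
br_date <- function(x) as.Date(x, tz = BR_TZ)

# Midnight (start of day) of a civil date, as an instant.
br_midnight <- function(date) {
  as.POSIXct(paste(format(date), "00:00:00"), tz = BR_TZ)
}

stop_br <- function(...) stop(..., call. = FALSE)

warn_br <- function(...) warning(..., call. = FALSE)

# FNV-1a hash of an R object's serialized bytes, as 8 hex digits.  Used to
# stamp pipeline outputs with the configuration that produced them without
# depending on an external digest library.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (varies with R version string)
  if (length(bytes) > 30) bytes <- bytes[-seq_len(30)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
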
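# Internal helpers shared across modules.

# Half-up rounding to `digits` decimals, for display values where the
# conventional clinical rounding (2.45 -> 2.5) is wanted rather than
# banker's rounding.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_clock <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = "UTC"))
  if (is.character(x)) {
    out <- suppressWarnings(as.POSIXct(x, tz = "UTC",
                                       tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                      "%Y-%m-%d %H:%M:%S",
                                                      "%Y-%m-%d")))
    if (any(is.na(out) & !is.na(x))) {
      abort(sprintf("Cannot parse %s: %s", what,
                    paste(x[is.na(out) & !is.na(x)], collapse = ", ")))
    }
    return(out)
  }
  abort(sprintf("Invalid %s of class %s", what, paste(class(x), collapse = "/")))
}

as_day <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  if (is.logical(x) && all(is.na(x))) return(as.Date(x))
  if (inherits(x, "POSIXct")) return(as.Date(x, tz = "UTC"))
  if (is.character(x)) {
    out <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
    if (any(is.na(out) & !is.na(x) & x != "")) {
      abort(sprintf("Cannot parse %s: %s", what,
                    paste(x[is.na(out) & !is.na(x)], collapse = ", ")))
    }
    return(out)
  }
  abort(sprintf("Invalid %s of class %s", what, paste(class(x), collapse = "/")))
}

iso_day <- function(x) ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%d"))
iso_clock <- function(x) ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%dT%H:%M:%S"))

compact_chr <- function(x) x[!is.na(x) & nzchar(x)]
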
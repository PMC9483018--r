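# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom data.table := .N .SD data.table as.data.table setDT setDF
#'   setorder setnames fwrite fread setattr copy rbindlist
NULL

# Classed condition constructors so callers can distinguish configuration
# problems from parse problems programmatically.
cw_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "chartward_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

cw_config_error <- function(fmt, ...) cw_stop("chartward_config_error", fmt, ...)
cw_parse_error  <- function(fmt, ...) cw_stop("chartward_parse_error", fmt, ...)
cw_version_error <- function(fmt, ...) cw_stop("chartward_version_error", fmt, ...)
cw_resource_error <- function(fmt, ...) cw_stop("chartward_resource_error", fmt, ...)

# All timestamps in the package are POSIXct in UTC.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

# Parse ISO-8601 "YYYY-MM-DDTHH:MM:SSZ" strings; empty strings -> NA.
parse_iso8601 <- function(x) {
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  nz <- !is.na(x) & nzchar(x)
  if (any(nz)) {
    parsed <- as.POSIXct(x[nz], format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    bad <- is.na(parsed)
    if (any(bad)) {
      cw_parse_error("unparseable ISO-8601 timestamp at row %d: '%s'",
                     which(nz)[bad][1], x[nz][bad][1])
    }
    out[nz] <- parsed
  }
  out
}

format_iso8601 <- function(ts) {
  out <- rep("", length(ts))
  ok <- !is.na(ts)
  out[ok] <- format(as_utc(ts[ok]), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out
}

hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar_prob <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    cw_config_error("'%s' must be a single number in [0, 1], got %s", name,
                    paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# Run code with a private RNG stream so simulation never perturbs (and is
# never perturbed by) the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is_scalar_number(seed)) cw_config_error("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
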
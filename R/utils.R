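# Internal helpers: input validation, unit parsing, small formatting utilities.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nmrbind_invalid_input", "invalidInput")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nmrbind_config_error", "configError")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nmrbind_io_error", "ioError")))
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
    stop_invalid("'%s' must be finite numeric, got %s", name,
                 paste(utils::head(format(x), 3L), collapse = ", "))
  invisible(x)
}

.check_pos <- function(x, name) {
  .check_finite(x, name)
  if (any(x <= 0)) stop_invalid("'%s' must be > 0", name)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  .check_finite(x, name)
  if (any(x < 0)) stop_invalid("'%s' must be >= 0", name)
  invisible(x)
}

.check_prob <- function(x, name) {
  .check_finite(x, name)
  if (any(x < 0 | x > 1)) stop_invalid("'%s' must lie in [0, 1]", name)
  invisible(x)
}

#' Parse a concentration with an optional unit suffix
#'
#' Converts strings such as `"5 nM"`, `"0.5mM"`, `"1e-6 M"` to mol/L.
#' Plain numbers (numeric or numeric strings) are taken to be mol/L already.
#' Recognised suffixes: `M`, `mM`, `uM` (or `µM`), `nM`, `pM`.
#'
#' @param x character or numeric vector.
#' @return numeric vector of concentrations in mol/L.
#' @examples
#' parse_concentration(c("5 nM", "0.5 mM", "1uM"))
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) stop_invalid("concentration must be numeric or character")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  out <- vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(M|mM|uM|µM|nM|pM)?$", s))[[1]]
    if (length(m) == 0L || m[2] == "")
      stop_invalid("cannot parse concentration '%s'", s)
    val <- suppressWarnings(as.numeric(m[2]))
    if (!is.finite(val)) stop_invalid("cannot parse concentration '%s'", s)
    unit <- if (m[3] == "") "M" else m[3]
    val * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
  out
}

# Format a numeric column so that write/read round-trips are exact.
.fmt_full <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
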
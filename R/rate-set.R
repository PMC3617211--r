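#' Kinetic rate set for the three-state pathway model
#'
#' The pathway is modeled as a continuous-time linear kinetic system over three
#' states: damage substrate `S`, intermediate `I` (potentially toxic) and
#' repaired product `P`. Five mass-action rate constants define the scheme:
#'
#' * `k1`   — `S -> I`, first forward step (enzyme F1)
#' * `k_m1` — `I -> S`, first backward step (enzyme R1)
#' * `k2`   — `I -> P`, second forward step (enzyme F2)
#' * `k_m2` — `P -> I`, second backward step (enzyme R2)
#' * `k3`   — `S -> P`, compensatory route (enzyme EC)
#'
#' Time units are arbitrary ("per unit time"); only rate ratios matter for the
#' long-time behavior.
#'
#' @param k1,k_m1,k2,k_m2,k3 Non-negative finite rate constants; at least one
#'   must be positive.
#' @return An object of class `rate_set`: a named numeric vector of length 5.
#' @examples
#' rate_set(1, 0.1, 1, 0.1, 0.1)
#' @export
rate_set <- function(k1, k_m1, k2, k_m2, k3) {
  r <- c(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2, k3 = k3)
  validate_rate_set(r)
  structure(r, class = "rate_set")
}

rate_names <- c("k1", "k_m1", "k2", "k_m2", "k3")

#' @noRd
validate_rate_set <- function(r) {
  if (length(r) != 5 || !is.numeric(r)) {
    stop("a rate set needs the five rates k1, k_m1, k2, k_m2, k3", call. = FALSE)
  }
  if (anyNA(r) || any(!is.finite(r))) {
    stop("invalid rate: all rates must be finite numbers", call. = FALSE)
  }
  if (any(r < 0)) {
    stop("invalid rate: rates must be non-negative", call. = FALSE)
  }
  if (all(r == 0)) {
    stop("invalid rate: at least one rate must be positive", call. = FALSE)
  }
  invisible(r)
}

#' Coerce to a rate set
#'
#' Accepts a `rate_set`, a named numeric vector or a named list (or a one-row
#' data frame) carrying the five rates.
#'
#' @param x Object to coerce.
#' @return A `rate_set`.
#' @export
as_rate_set <- function(x) {
  if (inherits(x, "rate_set")) {
    return(x)
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[rate_names])
  }
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 5) {
    names(x) <- rate_names
  }
  if (!all(rate_names %in% names(x))) {
    stop("need named entries k1, k_m1, k2, k_m2, k3", call. = FALSE)
  }
  rate_set(x[["k1"]], x[["k_m1"]], x[["k2"]], x[["k_m2"]], x[["k3"]])
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>  S -k1-> I -k2-> P  (back: k_m1, k_m2; compensatory S -k3-> P)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
as.data.frame.rate_set <- function(x, ...) {
  as.data.frame(as.list(unclass(x)))
}

#' Tidy a rate set into a one-row tibble
#'
#' @param x A `rate_set`.
#' @param ... Unused.
#' @return A tibble with columns `k1, k_m1, k2, k_m2, k3`.
#' @export
tidy.rate_set <- function(x, ...) {
  tibble::as_tibble(as.list(unclass(x)))
}

#' Read / write a rate configuration file
#'
#' Rate sets are stored as flat `key: value` text, one rate per line, e.g.
#' `k1: 1`. Blank lines and lines starting with `#` are ignored. Unknown keys
#' are rejected.
#'
#' @param path File path.
#' @return `read_rate_config()` returns a `rate_set`;
#'   `write_rate_config()` returns `path` invisibly.
#' @export
read_rate_config <- function(path) {
  kv <- read_flat_config(path)
  unknown <- setdiff(names(kv), rate_names)
  if (length(unknown) > 0) {
    stop("unknown rate config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(rate_names, names(kv))
  if (length(missing) > 0) {
    stop("missing rate config keys: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(kv[rate_names]))
  if (anyNA(vals)) stop("non-numeric rate value in ", path, call. = FALSE)
  as_rate_set(stats::setNames(vals, rate_names))
}

#' @rdname read_rate_config
#' @param rates A `rate_set` to write.
#' @export
write_rate_config <- function(rates, path) {
  rates <- as_rate_set(rates)
  writeLines(sprintf("%s: %.17g", names(rates), unclass(rates)), path)
  invisible(path)
}

# Flat `key: value` parser shared by rate configs and the CLI --config option.
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  bad <- !grepl(":", lines, fixed = TRUE)
  if (any(bad)) {
    stop("malformed config line (expected 'key: value'): ", lines[bad][1], call. = FALSE)
  }
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  if (anyDuplicated(keys)) {
    stop("duplicate config key: ", keys[duplicated(keys)][1], call. = FALSE)
  }
  stats::setNames(vals, keys)
}
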
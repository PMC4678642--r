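#' Continuous intervals backing qualitative levels
#'
#' A qualitative level can be declared equivalent to a continuous interval of
#' the quantity it abstracts (a concentration in mmol/l, or a flux in
#' mmol/(gDW h)). The interval carries open/closed flags on each endpoint so a
#' partition such as `[0,0]`, `]0, 0.6]`, `]0.6, +inf[` is expressible without
#' overlap. An interval with `lower == upper` must be closed on both sides.
#'
#' @param lower,upper endpoints; `upper` may be `Inf`.
#' @param lower_open,upper_open whether the corresponding endpoint is excluded.
#' @return an object of class `qf_interval`.
#' @examples
#' qf_interval(0, 0.6, lower_open = TRUE)
#' @export
qf_interval <- function(lower, upper, lower_open = FALSE, upper_open = FALSE) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (lower > upper) stop("interval lower bound exceeds upper bound", call. = FALSE)
  if (lower == upper && (lower_open || upper_open)) {
    stop("a degenerate interval [a,a] cannot have open endpoints", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 lower_open = isTRUE(lower_open), upper_open = isTRUE(upper_open)),
            class = "qf_interval")
}

#' @export
format.qf_interval <- function(x, ...) {
  up <- if (is.infinite(x$upper)) "+inf" else format(x$upper)
  paste0(if (x$lower_open) "]" else "[", format(x$lower), ",", up,
         if (x$upper_open) "[" else "]")
}

#' @export
print.qf_interval <- function(x, ...) {
  cat("<interval ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Test whether a value lies in an interval
#' @param iv a [qf_interval()].
#' @param x a numeric value.
#' @return `TRUE` or `FALSE`.
#' @export
interval_contains <- function(iv, x) {
  lo_ok <- if (iv$lower_open) x > iv$lower else x >= iv$lower
  hi_ok <- if (iv$upper_open) x < iv$upper else x <= iv$upper
  lo_ok && hi_ok
}

# TRUE if the two intervals share at least one point (openness respected).
intervals_overlap <- function(a, b) {
  lo <- max(a$lower, b$lower)
  hi <- min(a$upper, b$upper)
  if (lo > hi) return(FALSE)
  if (lo < hi) return(TRUE)
  # single shared point: open at that point in either interval excludes it
  at_lo_a <- if (lo == a$lower) !a$lower_open else !a$upper_open
  at_lo_b <- if (lo == b$lower) !b$lower_open else !b$upper_open
  at_lo_a && at_lo_b
}

#' Parse a state/interval equivalence note
#'
#' Equivalence declarations live in the notes of a qualitative species, one
#' directive per line:
#'
#' ```
#' STATE 0 : [0, 0]
#' STATE 1 : ]0, 0.6]
#' STATE 2 : ]0.6, +inf[
#' ```
#'
#' Both the bracket dialect `]a,b]` and the parenthesis dialect `(a,b]` denote
#' an open endpoint; `+inf` (or `inf`) denotes an unbounded upper end. Blank
#' lines and `#` comments are ignored; whitespace is free.
#'
#' @param text the note body as a single string (or a character vector of
#'   lines).
#' @return a named list mapping each declared level (as `"0"`, `"1"`, ...) to a
#'   [qf_interval()]. Declared intervals must be pairwise disjoint.
#' @export
parse_equivalence_note <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- list()
  pat <- paste0("^\\s*STATE\\s+([0-9]+)\\s*:\\s*([\\[\\]\\(])\\s*",
                "(-?[0-9.]+(?:[eE][+-]?[0-9]+)?)\\s*,\\s*",
                "(\\+?inf|-?[0-9.]+(?:[eE][+-]?[0-9]+)?)\\s*([\\[\\]\\)])\\s*$")
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    if (!grepl("[^[:space:]]", line)) next
    m <- regmatches(line, regexec(pat, line, ignore.case = TRUE,
                                  perl = TRUE))[[1]]
    if (length(m) == 0) {
      stop("malformed equivalence directive at line ", i, ": '",
           trimws(lines[[i]]), "'", call. = FALSE)
    }
    level <- m[2]
    if (!is.null(out[[level]])) {
      stop("duplicate equivalence for level ", level, " at line ", i,
           call. = FALSE)
    }
    lower_open <- m[3] == "]" || m[3] == "("
    upper <- if (grepl("inf", m[5], ignore.case = TRUE)) Inf else as.numeric(m[5])
    upper_open <- m[6] == "[" || m[6] == ")"
    out[[level]] <- qf_interval(as.numeric(m[4]), upper,
                                lower_open = lower_open,
                                upper_open = upper_open)
  }
  check_equivalences_disjoint(out)
  out[order(as.integer(names(out)))]
}

check_equivalences_disjoint <- function(eq) {
  lv <- names(eq)
  if (length(lv) > 1) {
    for (i in seq_len(length(lv) - 1)) {
      for (j in seq(i + 1, length(lv))) {
        if (intervals_overlap(eq[[i]], eq[[j]])) {
          stop("equivalence intervals for levels ", lv[i], " and ", lv[j],
               " overlap (", format(eq[[i]]), " vs ", format(eq[[j]]), ")",
               call. = FALSE)
        }
      }
    }
  }
  invisible(eq)
}

# Serialise an equivalence list back to note lines.
equivalences_to_note <- function(eq) {
  vapply(names(eq), function(lv) {
    paste0("STATE ", lv, " : ", format(eq[[lv]]))
  }, character(1))
}

# Level whose interval contains `value`; ties across dialect-mixed shared
# boundaries resolve to the lowest matching level.
level_for_value <- function(eq, value, id = "?") {
  lv <- as.integer(names(eq))
  ord <- order(lv)
  for (k in ord) {
    if (interval_contains(eq[[k]], value)) return(lv[k])
  }
  stop("value ", value, " for '", id,
       "' is contained in no declared equivalence interval", call. = FALSE)
}
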
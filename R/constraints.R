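#' Parse a plain-text constraint file
#'
#' The constraint file carries the objective and user overrides, one directive
#' per line; `#` starts a comment:
#'
#' ```
#' obj : MAX(R_biomass)
#' M_glc_e  11.1        # a single value
#' R_EX_o2  -20  0      # an interval
#' ```
#'
#' A single value on a reaction fixes both bounds; on a regulatory component
#' it is an initial-value override (quantitative if the species declares
#' equivalences, in mmol/l for concentrations); on an external metabolite it
#' is a concentration. A two-value line always sets an interval.
#'
#' @param path path to the constraint file.
#' @return a `constraint_file` list with `objective` (`NULL` or
#'   `list(expression = <named numeric over reaction ids or character id>,
#'   sense = "max"|"min")`) and `overrides` (tibble `id`, `lb`, `ub`,
#'   `single`).
#' @export
parse_constraint_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  objective <- NULL
  ids <- character(0); lb <- ub <- numeric(0); single <- logical(0)
  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[[i]]))
    if (!nzchar(line)) next
    mo <- regexec("^obj\\s*:\\s*(MAX|MIN)\\s*\\(([^)]+)\\)\\s*$", line,
                  ignore.case = TRUE)
    m <- regmatches(line, mo)[[1]]
    if (length(m)) {
      if (!is.null(objective)) {
        stop("duplicate objective at line ", i, call. = FALSE)
      }
      objective <- list(expression = parse_objective_expr(trimws(m[3]), i),
                        sense = tolower(m[2]))
      next
    }
    parts <- strsplit(line, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (!(length(parts) %in% c(2L, 3L)) || anyNA(vals)) {
      stop("malformed constraint at line ", i, ": '", trimws(lines[[i]]), "'",
           call. = FALSE)
    }
    if (parts[1] %in% ids) {
      stop("duplicate constraint for '", parts[1], "' at line ", i,
           call. = FALSE)
    }
    ids <- c(ids, parts[1])
    single <- c(single, length(vals) == 1L)
    lb <- c(lb, vals[1])
    ub <- c(ub, vals[length(vals)])
    if (vals[1] > vals[length(vals)]) {
      stop("lower bound exceeds upper bound at line ", i, call. = FALSE)
    }
  }
  structure(list(objective = objective,
                 overrides = tibble::tibble(id = ids, lb = lb, ub = ub,
                                            single = single)),
            class = "constraint_file")
}

# "R_bio" or "2 R_a + R_b" -> named coefficient vector
parse_objective_expr <- function(txt, line_no) {
  terms <- strsplit(txt, "\\+")[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec(
      "^(-?[0-9.]+(?:[eE][+-]?[0-9]+)?\\s+)?([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
    if (!length(m)) {
      stop("malformed objective term '", tm, "' at line ", line_no,
           call. = FALSE)
    }
    cf <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    out[m[3]] <- cf
  }
  out
}

#' Apply constraint-file overrides to a metabolic model
#'
#' Reaction overrides replace the SBML bounds (the file is an explicit user
#' override); a single value fixes both bounds. The objective, if present,
#' replaces the model's. Identifiers that are not reactions are returned
#' untouched for the regulatory layer (initial values / concentrations).
#'
#' @param model a [metabolic_model()].
#' @param cons a `constraint_file` from [parse_constraint_file()].
#' @return list: `model` (updated) and `regulatory_overrides` (named list of
#'   non-reaction single values, for [run_rsa()]).
#' @export
apply_constraint_file <- function(model, cons) {
  reg <- list()
  ov <- cons$overrides
  for (i in seq_len(nrow(ov))) {
    id <- ov$id[[i]]
    if (id %in% names(model$reactions)) {
      model$reactions[[id]]$lb <- ov$lb[[i]]
      model$reactions[[id]]$ub <- ov$ub[[i]]
    } else {
      if (!ov$single[[i]]) {
        stop("interval override for '", id,
             "', which is not a model reaction", call. = FALSE)
      }
      reg[[id]] <- ov$lb[[i]]
    }
  }
  if (!is.null(cons$objective)) {
    model$objective <- normalise_objective(cons$objective$expression,
                                           names(model$reactions))
    model$sense <- cons$objective$sense
  }
  list(model = model, regulatory_overrides = reg)
}
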
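#' Logical expressions over qualitative species levels
#'
#' Update rules and gene-protein-reaction (GPR) associations are boolean
#' expression trees whose leaves compare a species level against an integer
#' constant (or are the literals TRUE/FALSE) and whose internal nodes are
#' AND / OR / NOT. `lx_cmp()`, `lx_and()`, `lx_or()`, `lx_not()` and
#' `lx_const()` build such trees programmatically; [parse_logic()] builds them
#' from text.
#'
#' @param species species (or gene) identifier referenced by the comparison.
#' @param cmp comparison operator, one of `"=="`, `"!="`, `">="`, `"<="`,
#'   `">"`, `"<"`.
#' @param value integer level the species is compared against.
#' @return a logic-expression node (a plain list with an `op` field).
#' @examples
#' e <- lx_and(lx_cmp("glc", ">=", 1), lx_not(lx_cmp("lac", ">=", 1)))
#' evaluate_expr(e, c(glc = 1L, lac = 0L))
#' @export
lx_cmp <- function(species, cmp, value) {
  cmp <- match.arg(cmp, c("==", "!=", ">=", "<=", ">", "<"))
  stopifnot(is.character(species), length(species) == 1L)
  list(op = "cmp", species = species, cmp = cmp, value = as.integer(value))
}

#' @rdname lx_cmp
#' @param ... child expressions.
#' @export
lx_and <- function(...) list(op = "and", args = list(...))

#' @rdname lx_cmp
#' @export
lx_or <- function(...) list(op = "or", args = list(...))

#' @rdname lx_cmp
#' @param x child expression.
#' @export
lx_not <- function(x) list(op = "not", arg = x)

#' @rdname lx_cmp
#' @export
lx_const <- function(value) list(op = "const", value = isTRUE(value))

#' Evaluate a logic expression against a network state
#'
#' @param expr a logic expression (see [lx_cmp()]).
#' @param state a complete network state: named integer vector of species
#'   levels.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_expr <- function(expr, state) {
  op <- expr$op
  if (op == "cmp") {
    i <- match(expr$species, names(state))
    if (is.na(i)) {
      stop("expression references species '", expr$species,
           "' absent from the state", call. = FALSE)
    }
    lvl <- state[[i]]
    return(switch(expr$cmp,
      "==" = lvl == expr$value,
      "!=" = lvl != expr$value,
      ">=" = lvl >= expr$value,
      "<=" = lvl <= expr$value,
      ">"  = lvl > expr$value,
      "<"  = lvl < expr$value))
  }
  if (op == "and") {
    for (a in expr$args) if (!evaluate_expr(a, state)) return(FALSE)
    return(TRUE)
  }
  if (op == "or") {
    for (a in expr$args) if (evaluate_expr(a, state)) return(TRUE)
    return(FALSE)
  }
  if (op == "not") return(!evaluate_expr(expr$arg, state))
  if (op == "const") return(expr$value)
  stop("unknown expression operator '", op, "'", call. = FALSE)
}

#' Species identifiers referenced by a logic expression
#' @inheritParams evaluate_expr
#' @return character vector of distinct species ids (possibly empty).
#' @export
expr_species <- function(expr) {
  switch(expr$op,
    cmp   = expr$species,
    and   = unique(unlist(lapply(expr$args, expr_species))),
    or    = unique(unlist(lapply(expr$args, expr_species))),
    not   = expr_species(expr$arg),
    const = character(0))
}

# Largest integer constant compared against `id` anywhere in `expr`; -Inf if none.
expr_max_level <- function(expr, id) {
  switch(expr$op,
    cmp   = if (identical(expr$species, id)) expr$value else -Inf,
    and   = ,
    or    = max(c(-Inf, vapply(expr$args, expr_max_level, numeric(1), id = id))),
    not   = expr_max_level(expr$arg, id),
    const = -Inf)
}

#' Render a logic expression as text
#'
#' Produces the textual dialect accepted by [parse_logic()]:
#' `(glc >= 1 and not (lac >= 1)) or false`.
#' @inheritParams evaluate_expr
#' @return a single character string.
#' @export
expr_to_text <- function(expr) {
  switch(expr$op,
    cmp   = paste(expr$species, expr$cmp, expr$value),
    and   = paste0("(", paste(vapply(expr$args, expr_to_text, character(1)),
                              collapse = " and "), ")"),
    or    = paste0("(", paste(vapply(expr$args, expr_to_text, character(1)),
                              collapse = " or "), ")"),
    not   = paste0("not (", expr_to_text(expr$arg), ")"),
    const = if (expr$value) "true" else "false")
}

#' Parse a logic expression from text
#'
#' Recognises `and`/`&`, `or`/`|`, `not`/`!`, parentheses, the literals
#' `true`/`false`, comparisons `id OP int` with OP in
#' `== != >= <= > <`, and bare identifiers. A bare identifier `g` is shorthand
#' for `g >= 1` ("active at any positive level"), which is the convention used
#' by GPR strings such as `"(g1 and g2) or g3"`.
#'
#' @param text the expression as a single string.
#' @return a logic expression.
#' @examples
#' parse_logic("(g1 and g2) or g3")
#' parse_logic("glc >= 2 & !(lac >= 1)")
#' @export
parse_logic <- function(text) {
  toks <- lx_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- lx_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("unexpected token '", st$toks[[st$pos]]$text,
         "' in logic expression: ", text, call. = FALSE)
  }
  expr
}

lx_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "==|!=|>=|<=|>|<|\\(|\\)|&&|\\|\\||&|\\||!|[A-Za-z_][A-Za-z0-9_]*|-?[0-9]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("empty logic expression", call. = FALSE)
  pieces <- regmatches(text, gregexpr(pat, text))[[1]]
  # anything not matched must be whitespace
  residue <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", residue)) {
    stop("unrecognised characters in logic expression: '",
         gsub("[[:space:]]", "", residue), "'", call. = FALSE)
  }
  lapply(pieces, function(p) {
    low <- tolower(p)
    type <-
      if (low %in% c("and", "&", "&&")) "and"
      else if (low %in% c("or", "|", "||")) "or"
      else if (low %in% c("not", "!")) "not"
      else if (low %in% c("true", "false")) "const"
      else if (grepl("^-?[0-9]+$", p)) "int"
      else if (p %in% c("==", "!=", ">=", "<=", ">", "<")) "op"
      else if (p %in% c("(", ")")) p
      else "id"
    list(type = type, text = p)
  })
}

lx_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

lx_parse_or <- function(st) {
  args <- list(lx_parse_and(st))
  while (!is.null(tk <- lx_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(lx_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

lx_parse_and <- function(st) {
  args <- list(lx_parse_unary(st))
  while (!is.null(tk <- lx_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(lx_parse_unary(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

lx_parse_unary <- function(st) {
  tk <- lx_peek(st)
  if (is.null(tk)) stop("unexpected end of logic expression", call. = FALSE)
  if (tk$type == "not") {
    st$pos <- st$pos + 1L
    return(lx_not(lx_parse_unary(st)))
  }
  lx_parse_primary(st)
}

lx_parse_primary <- function(st) {
  tk <- lx_peek(st)
  if (is.null(tk)) stop("unexpected end of logic expression", call. = FALSE)
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    e <- lx_parse_or(st)
    tk2 <- lx_peek(st)
    if (is.null(tk2) || tk2$type != ")") {
      stop("missing closing parenthesis in logic expression", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(e)
  }
  if (tk$type == "const") {
    st$pos <- st$pos + 1L
    return(lx_const(tolower(tk$text) == "true"))
  }
  if (tk$type == "id") {
    st$pos <- st$pos + 1L
    nxt <- lx_peek(st)
    if (!is.null(nxt) && nxt$type == "op") {
      st$pos <- st$pos + 1L
      val <- lx_peek(st)
      if (is.null(val) || val$type != "int") {
        stop("comparison against non-integer after '", tk$text, " ", nxt$text,
             "'", call. = FALSE)
      }
      st$pos <- st$pos + 1L
      return(lx_cmp(tk$text, nxt$text, as.integer(val$text)))
    }
    return(lx_cmp(tk$text, ">=", 1L))  # bare identifier: active at level >= 1
  }
  stop("unexpected token '", tk$text, "' in logic expression", call. = FALSE)
}
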
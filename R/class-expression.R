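#' Class expressions: named classes and genus-differentia compositions
#'
#' A class expression is either a named class (`xp_named`) or a composition
#' (`xp_composed`): a genus class restricted by one or more relation-filler
#' differentia, written in caret syntax as `genus^relation(filler)`. The
#' bearer of "abnormal Purkinje cell dendrite morphology" is the composition
#' `GO:0030425^part_of(CL:0000121)` - a dendrite that is part of a Purkinje
#' cell. Fillers are themselves class expressions, so compositions nest.
#'
#' @param id class identifier (or an unresolved label awaiting curation).
#' @return An object of class `xp_expr`.
#' @export
xp_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id), class = c("xp_named", "xp_expr"))
}

#' @param genus class identifier of the genus.
#' @param differentia non-empty list of `list(relation =, filler =)` pairs
#'   where each filler is an `xp_expr`.
#' @rdname xp_named
#' @export
xp_composed <- function(genus, differentia) {
  if (!length(differentia)) {
    stop_phenoxp("a composed expression needs at least one differentium",
                 "phenoxp_malformed_expression")
  }
  differentia <- map(differentia, function(d) {
    filler <- d$filler
    if (is.character(filler)) filler <- xp_named(filler)
    list(relation = d$relation, filler = filler)
  })
  structure(list(genus = genus, differentia = differentia),
            class = c("xp_composed", "xp_expr"))
}

as_xp_expr <- function(x) {
  if (inherits(x, "xp_expr")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^", x, fixed = TRUE)) return(parse_class_expression(x))
    return(xp_named(x))
  }
  stop_phenoxp("cannot interpret object as a class expression",
               "phenoxp_malformed_expression")
}

is_named_expr <- function(x) inherits(x, "xp_named")

#' Canonical form of a class expression
#'
#' Differentia are sorted by (relation, rendered filler) so that two
#' expressions are equal iff their canonical forms are identical.
#'
#' @param x an `xp_expr`.
#' @return An `xp_expr` in canonical order.
#' @export
canonicalize_expr <- function(x) {
  if (is_named_expr(x)) return(x)
  diffs <- map(x$differentia, function(d) {
    list(relation = d$relation, filler = canonicalize_expr(d$filler))
  })
  keys <- map_chr(diffs, ~ paste(.x$relation, format(.x$filler)))
  xp_composed(x$genus, diffs[order(keys, method = "radix")])
}

#' @export
format.xp_expr <- function(x, ...) {
  if (is_named_expr(x)) return(x$id)
  paste0(x$genus, paste0(
    map_chr(x$differentia,
            ~ paste0("^", .x$relation, "(", format(.x$filler), ")")),
    collapse = ""
  ))
}

#' @export
print.xp_expr <- function(x, ...) {
  cat("<xp_expr> ", format(x), "\n", sep = "")
  invisible(x)
}

expr_equal <- function(a, b) {
  identical(format(canonicalize_expr(a)), format(canonicalize_expr(b)))
}

# All named identifiers mentioned anywhere in an expression.
expr_ids <- function(x) {
  if (is_named_expr(x)) return(x$id)
  c(x$genus, unlist(map(x$differentia, ~ expr_ids(.x$filler))))
}

#' Deterministic identifier for a materialized composed expression
#'
#' Composed expressions are never written to OBO files directly; they are
#' materialized as stanzas first, under a stable content-hash id so repeated
#' materialization yields the same identifier across runs.
#'
#' @param x an `xp_expr`.
#' @return A `XP:`-prefixed identifier for composed expressions, or the plain
#'   id for named ones.
#' @export
expression_id <- function(x) {
  if (is_named_expr(x)) return(x$id)
  paste0("XP:", substr(hash(format(canonicalize_expr(x))), 1, 10))
}

#' Parse caret composition syntax
#'
#' Parses `A^rel(B)` expressions, nestable as in
#' `dendrite^part_of(Purkinje_cell)`; multiple differentia chain as
#' `A^r1(B)^r2(C)`. Unbalanced syntax raises an error reporting the character
#' offset.
#'
#' @param text expression text.
#' @return An `xp_expr`.
#' @export
parse_class_expression <- function(text) {
  state <- new.env(parent = emptyenv())
  state$s <- text
  state$pos <- 1L
  expr <- parse_expr_at(state)
  if (state$pos <= nchar(state$s)) {
    stop_phenoxp(
      sprintf("unexpected character '%s' at offset %d in expression '%s'",
              substr(state$s, state$pos, state$pos), state$pos, text),
      "phenoxp_syntax"
    )
  }
  expr
}

peek <- function(state) {
  if (state$pos > nchar(state$s)) "" else substr(state$s, state$pos, state$pos)
}

take_until <- function(state, stops) {
  start <- state$pos
  while (state$pos <= nchar(state$s) && !(peek(state) %in% stops)) {
    state$pos <- state$pos + 1L
  }
  str_trim(substr(state$s, start, state$pos - 1L))
}

parse_expr_at <- function(state) {
  atom <- take_until(state, c("^", "(", ")"))
  if (!nzchar(atom)) {
    stop_phenoxp(
      sprintf("empty class name at offset %d in expression '%s'",
              state$pos, state$s),
      "phenoxp_syntax"
    )
  }
  diffs <- list()
  while (peek(state) == "^") {
    state$pos <- state$pos + 1L
    rel <- take_until(state, c("(", "^", ")"))
    if (peek(state) != "(" || !nzchar(rel)) {
      stop_phenoxp(
        sprintf("expected 'relation(' at offset %d in expression '%s'",
                state$pos, state$s),
        "phenoxp_syntax"
      )
    }
    state$pos <- state$pos + 1L
    filler <- parse_expr_at(state)
    if (peek(state) != ")") {
      stop_phenoxp(
        sprintf("unbalanced parenthesis at offset %d in expression '%s'",
                state$pos, state$s),
        "phenoxp_syntax"
      )
    }
    state$pos <- state$pos + 1L
    diffs <- c(diffs, list(list(relation = rel, filler = filler)))
  }
  if (!length(diffs)) xp_named(atom) else xp_composed(atom, diffs)
}
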
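# Atom-selection mini-language.
#
# Grammar (case-sensitive keywords, whitespace-separated tokens):
#   expr    := or_expr
#   or_expr := and_expr ('or' and_expr)*
#   and_expr:= not_expr ('and' not_expr)*
#   not_expr:= 'not' not_expr | primary
#   primary := '(' expr ')' | clause
#   clause  := 'resid' range+ | 'resname' name+ | 'name' name+
#            | 'segment' label | 'category' cat
# Ranges are integers or 'a-b' / 'a:b' spans; multiple values after a clause
# keyword are OR-ed together.

.SEL_KEYWORDS <- c("resid", "resname", "name", "segment", "category",
                   "and", "or", "not", "(", ")")

.tokenize_selection <- function(expression) {
  expr <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[toks != ""]
}

#' Select atoms with the selection mini-language
#'
#' Evaluates a selection expression against a topology and returns the
#' matching atom positions. Clauses (\code{resid}, \code{resname},
#' \code{name}, \code{segment}, \code{category}) combine with \code{and},
#' \code{or}, \code{not} and parentheses; e.g.
#' \code{"resid 309 and name OE1 OE2"} picks the two carboxyl oxygens of
#' Glu309, and \code{"segment M2 and category protein"} all atoms of helix
#' M2. An empty result is legal.
#'
#' @param topology an [md_topology()].
#' @param expression selection string.
#' @return an object of class \code{atom_selection} with fields
#'   \code{indices} (sorted unique 1-based atom positions) and
#'   \code{expression}.
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "md_topology"))
  tokens <- .tokenize_selection(expression)
  if (length(tokens) == 0) stop("parse error at position 1: empty selection expression")
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  mask <- .sel_or(state, topology)
  if (state$pos <= length(tokens)) {
    stop(sprintf("parse error at token %d: unexpected '%s'",
                 state$pos, tokens[state$pos]))
  }
  structure(list(indices = which(mask), expression = expression),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection: %d atoms <%s>\n", length(x$indices), x$expression))
  invisible(x)
}

.sel_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}

.sel_take <- function(state) {
  tok <- .sel_peek(state)
  state$pos <- state$pos + 1L
  tok
}

.sel_or <- function(state, topo) {
  mask <- .sel_and(state, topo)
  while (identical(.sel_peek(state), "or")) {
    .sel_take(state)
    mask <- mask | .sel_and(state, topo)
  }
  mask
}

.sel_and <- function(state, topo) {
  mask <- .sel_not(state, topo)
  while (identical(.sel_peek(state), "and")) {
    .sel_take(state)
    mask <- mask & .sel_not(state, topo)
  }
  mask
}

.sel_not <- function(state, topo) {
  if (identical(.sel_peek(state), "not")) {
    .sel_take(state)
    return(!.sel_not(state, topo))
  }
  .sel_primary(state, topo)
}

.sel_primary <- function(state, topo) {
  tok <- .sel_peek(state)
  if (is.na(tok)) stop(sprintf("parse error at token %d: unexpected end of expression", state$pos))
  if (tok == "(") {
    .sel_take(state)
    mask <- .sel_or(state, topo)
    if (!identical(.sel_peek(state), ")")) {
      stop(sprintf("parse error at token %d: expected ')'", state$pos))
    }
    .sel_take(state)
    return(mask)
  }
  .sel_clause(state, topo)
}

.sel_values <- function(state) {
  vals <- character(0)
  repeat {
    tok <- .sel_peek(state)
    if (is.na(tok) || tok %in% .SEL_KEYWORDS) break
    vals <- c(vals, .sel_take(state))
  }
  vals
}

.sel_clause <- function(state, topo) {
  kw_pos <- state$pos
  kw <- .sel_take(state)
  at <- topo$atoms
  if (!kw %in% c("resid", "resname", "name", "segment", "category")) {
    stop(sprintf("parse error at token %d: unknown clause '%s'", kw_pos, kw))
  }
  vals <- .sel_values(state)
  if (length(vals) == 0) {
    stop(sprintf("parse error at token %d: clause '%s' needs at least one value",
                 state$pos, kw))
  }
  switch(kw,
    resid = {
      ids <- integer(0)
      for (v in vals) {
        m <- regmatches(v, regexec("^(-?[0-9]+)[-:](-?[0-9]+)$", v))[[1]]
        if (length(m) == 3) {
          ids <- c(ids, seq.int(as.integer(m[2]), as.integer(m[3])))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else {
          stop(sprintf("parse error at token %d: bad resid value '%s'", state$pos - 1L, v))
        }
      }
      at$residue_id %in% ids
    },
    resname = at$residue_name %in% vals,
    name = at$atom_name %in% vals,
    segment = {
      unknown <- setdiff(vals, names(topo$segments))
      if (length(unknown) > 0) {
        stop("lookup error: undefined segment label(s): ", paste(unknown, collapse = ", "))
      }
      at$residue_id %in% unlist(topo$segments[vals], use.names = FALSE)
    },
    category = {
      bad <- setdiff(vals, c("protein", "lipid", "water", "ion"))
      if (length(bad) > 0) {
        stop(sprintf("parse error: unknown category '%s'", paste(bad, collapse = ", ")))
      }
      at$category %in% vals
    }
  )
}
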
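# Gene-protein-reaction (GPR) boolean expressions.
#
# Grammar (case-insensitive keywords, parentheses, gene ids are any token
# that is not a keyword or parenthesis):
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := GENE | "(" expr ")"
# The parsed form is a nested list: a leaf is a gene id string; an internal
# node is list(op = "and"|"or", args = list(...)).

.gpr_tokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  text <- gsub("&&|&", " and ", text)
  text <- gsub("\\|\\||\\|", " or ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene association expression
#'
#' @param text A boolean expression over gene ids using `and`/`or` (also
#'   `&`/`|`) and parentheses. Empty or `NA` input yields `NULL`, meaning the
#'   reaction is unconditionally active (e.g., spontaneous reactions).
#' @return `NULL`, a gene id string, or a nested list tree with elements
#'   `op` (`"and"` or `"or"`) and `args`.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokens(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) {
      abort("malformed gene association: unexpected end of expression",
            class = "metoncokit_parse_error")
    }
    if (t == "(") {
      take()
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        abort("malformed gene association: missing ')'",
              class = "metoncokit_parse_error")
      }
      take()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      abort(paste0("malformed gene association near '", t, "'"),
            class = "metoncokit_parse_error")
    }
    take()
  }
  out <- parse_expr()
  if (pos <= length(toks)) {
    abort(paste0("malformed gene association: trailing '", toks[pos], "'"),
          class = "metoncokit_parse_error")
  }
  out
}

#' Genes referenced by a gene association
#'
#' @param gpr An expression string or a tree from [parse_gpr()].
#' @return Character vector of distinct gene ids (empty for an empty
#'   association).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr) && length(gpr) == 1L) gpr <- parse_gpr(gpr)
  walk <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(gpr))
}

#' Evaluate a gene association under a set of deleted genes
#'
#' An `and` node is active iff all children are active (enzyme complex); an
#' `or` node is active iff any child is active (isozymes); a leaf is active
#' iff the gene is not deleted; an empty association is always active.
#'
#' @param gpr An expression string or a tree from [parse_gpr()].
#' @param deleted Character vector of deleted gene ids.
#' @return `TRUE` if the reaction can still be catalysed, else `FALSE`.
#' @export
evaluate_gpr <- function(gpr, deleted = character(0)) {
  if (is.character(gpr) && length(gpr) == 1L) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(TRUE)
  ev <- function(node) {
    if (is.character(node)) return(!(node %in% deleted))
    vals <- vapply(node$args, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(gpr)
}
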
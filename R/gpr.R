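# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids with
# case-insensitive "and"/"or" and parentheses, e.g. "(g1 and g2) or g3".
# Parsed to a tree of list(op = "gene"/"and"/"or", ...); "or" binds loosest.

#' Parse a GPR rule string into an expression tree
#'
#' @param text rule text; gene identifiers, parentheses and the operators
#'   `and` / `or` (case-insensitive). An empty or all-whitespace string means
#'   "no rule" and returns `NULL`.
#' @return a GPR tree: leaves are `list(op = "gene", gene = <id>)`, internal
#'   nodes `list(op = "and"|"or", children = list(...))`, or `NULL`.
#' @examples
#' parse_gpr("(CAD and UMPS) or DHODH")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule: unexpected token '", st$toks[st$pos],
         "' in \"", text, "\"")
  }
  tree
}

.gpr_tokenize <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) == 0L) stop("malformed GPR rule: empty expression")
  toks
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.gpr_parse_or <- function(st) {
  kids <- list(.gpr_parse_and(st))
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    kids[[length(kids) + 1L]] <- .gpr_parse_and(st)
  }
  if (length(kids) == 1L) kids[[1L]] else list(op = "or", children = kids)
}

.gpr_parse_and <- function(st) {
  kids <- list(.gpr_parse_atom(st))
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    kids[[length(kids) + 1L]] <- .gpr_parse_atom(st)
  }
  if (length(kids) == 1L) kids[[1L]] else list(op = "and", children = kids)
}

.gpr_parse_atom <- function(st) {
  tk <- .gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of expression")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_parse_or(st)
    if (is.na(.gpr_peek(st)) || .gpr_peek(st) != ")") {
      stop("malformed GPR rule: missing closing parenthesis")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("malformed GPR rule: unexpected token '", tk, "'")
  }
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Genes referenced by a GPR rule
#'
#' @param rule parsed GPR tree (from [parse_gpr()]) or rule text.
#' @return character vector of unique gene ids (empty if no rule).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(character(0))
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes)))
}

#' Evaluate a GPR rule against boolean gene states
#'
#' Used for knockouts: genes present evaluate TRUE unless listed in
#' `knocked_out`.
#'
#' @param rule parsed GPR tree or rule text; `NULL`/empty means no rule and
#'   evaluates TRUE (the reaction needs no gene product).
#' @param knocked_out character vector of gene ids set to FALSE.
#' @return logical scalar.
#' @export
gpr_boolean <- function(rule, knocked_out = character(0)) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(TRUE)
  switch(rule$op,
    gene = !(rule$gene %in% knocked_out),
    and = all(vapply(rule$children, gpr_boolean, logical(1),
                     knocked_out = knocked_out)),
    or = any(vapply(rule$children, gpr_boolean, logical(1),
                    knocked_out = knocked_out)),
    stop("malformed GPR tree: unknown node type '", rule$op, "'")
  )
}

# Deparse a GPR tree back to canonical text (used by the SBML reader).
.gpr_deparse <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$op == "gene") return(rule$gene)
  parts <- vapply(rule$children, function(ch) {
    txt <- .gpr_deparse(ch)
    if (ch$op %in% c("and", "or") && ch$op != rule$op) paste0("(", txt, ")") else txt
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}
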
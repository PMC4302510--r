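#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a boolean expression over gene identifiers into an expression
#' tree.  The grammar accepts the operators `and`, `or`, `not`
#' (case-insensitive; the symbols `&`/`&&`, `|`/`||` and `!` are accepted
#' as synonyms) and parentheses, with the usual precedence
#' `not` > `and` > `or`.  Negation is part of the grammar because a
#' reaction may be catalyzed in the *absence* of a gene product (e.g. a
#' rule `g1 or not g2`), which makes the associated-reaction map
#' non-monotone in the knocked-out gene set.
#'
#' @param text a single rule string, e.g. `"(a and b) or c"`.
#' @return An object of class `gene_rule`: a nested list of nodes with
#'   `op` in `"gene"`, `"not"`, `"and"`, `"or"`.
#' @examples
#' r <- parse_gene_rule("g1 or not g2")
#' eval_gene_rule(r, c(g1 = FALSE, g2 = TRUE))  # FALSE
#' @export
parse_gene_rule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("GPR rule must be a single string")
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  rule <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    stop("syntax error in GPR rule at position ", tk$at,
         ": unexpected '", tk$text, "'")
  }
  attr(rule, "text") <- text
  attr(rule, "genes") <- sort_ids(rule_genes_(rule))
  class(rule) <- "gene_rule"
  rule
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|&&|\\|\\||&|\\||!|[A-Za-z0-9_.:'-]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("syntax error in GPR rule at position 1: empty rule")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # anything between tokens other than whitespace is illegal
  covered <- rep(FALSE, nchar(text))
  toks <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    piece <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
    low <- tolower(piece)
    type <- switch(low,
      "(" = "lpar", ")" = "rpar",
      "and" = "and", "&" = "and", "&&" = "and",
      "or" = "or", "|" = "or", "||" = "or",
      "not" = "not", "!" = "not",
      "ident")
    toks[[i]] <- list(type = type, text = piece, at = starts[i])
  }
  rest <- strsplit(text, "")[[1]][!covered]
  if (any(!grepl("^[[:space:]]$", rest))) {
    bad <- which(!covered & !grepl("[[:space:]]", strsplit(text, "")[[1]]))[1]
    stop("syntax error in GPR rule at position ", bad, ": unexpected '",
         substr(text, bad, bad), "'")
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, text)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_unary(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_unary(st, text)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_unary <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop("syntax error in GPR rule at position ", nchar(text) + 1L,
         ": unexpected end of rule")
  }
  if (tk$type == "not") {
    st$pos <- st$pos + 1L
    return(list(op = "not", arg = gpr_parse_unary(st, text)))
  }
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    cl <- gpr_peek(st)
    if (is.null(cl) || cl$type != "rpar") {
      stop("syntax error in GPR rule at position ",
           if (is.null(cl)) nchar(text) + 1L else cl$at,
           ": expected ')'")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "ident") {
    st$pos <- st$pos + 1L
    return(list(op = "gene", gene = tk$text))
  }
  stop("syntax error in GPR rule at position ", tk$at,
       ": unexpected '", tk$text, "'")
}

rule_genes_ <- function(node) {
  switch(node$op,
    gene = node$gene,
    not = rule_genes_(node$arg),
    unlist(lapply(node$args, rule_genes_), use.names = FALSE)
  )
}

#' Genes referenced by a GPR rule
#' @param rule a `gene_rule`.
#' @return character vector of gene identifiers (sorted, unique).
#' @export
rule_genes <- function(rule) {
  stopifnot(inherits(rule, "gene_rule"))
  attr(rule, "genes")
}

#' Evaluate a GPR rule under a truth assignment
#'
#' @param rule a `gene_rule` from [parse_gene_rule()].
#' @param assignment named logical vector; must cover every gene in the rule.
#' @return logical scalar.
#' @export
eval_gene_rule <- function(rule, assignment) {
  stopifnot(inherits(rule, "gene_rule"))
  miss <- setdiff(rule_genes(rule), names(assignment))
  if (length(miss)) {
    stop("assignment missing genes: ", paste(miss, collapse = ", "))
  }
  eval_rule_(rule, assignment)
}

eval_rule_ <- function(node, assignment) {
  switch(node$op,
    gene = as.logical(assignment[[node$gene]]),
    not = !eval_rule_(node$arg, assignment),
    and = all(vapply(node$args, eval_rule_, logical(1), assignment)),
    or = any(vapply(node$args, eval_rule_, logical(1), assignment))
  )
}

#' @export
format.gene_rule <- function(x, ...) deparse_rule_(x, top = TRUE)

#' @export
print.gene_rule <- function(x, ...) {
  cat("<gene_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

deparse_rule_ <- function(node, top = FALSE) {
  out <- switch(node$op,
    gene = node$gene,
    not = paste0("not ", wrap_(node$arg, c("and", "or"))),
    and = paste(vapply(node$args, wrap_, character(1), "or"), collapse = " and "),
    or = paste(vapply(node$args, wrap_, character(1), character(0)),
               collapse = " or ")
  )
  out
}

wrap_ <- function(node, parenthesize_ops) {
  s <- deparse_rule_(node)
  if (node$op %in% parenthesize_ops) paste0("(", s, ")") else s
}
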
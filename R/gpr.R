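## Gene-protein-reaction rules: boolean expressions over gene ids with
## AND/OR (case-insensitive) and parentheses. A knockout sets the gene's
## literal to FALSE; a reaction whose rule evaluates FALSE is disabled.

.gprTokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(character())
  regmatches(text, gregexpr(pat, text))[[1]]
}

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR expression such as \code{"(g1 and g2) or g3"}
#' into a nested list with elements \code{op} (\code{"and"}, \code{"or"}
#' or \code{"gene"}) and \code{args}. Keywords are case-insensitive;
#' any other token is a gene id. OR binds weaker than AND.
#'
#' @param text the rule string; \code{""} parses to NULL (no rule).
#' @return a parse tree (nested list), or NULL for an empty rule.
#' @examples
#' parseGPR("(g1 and g2) or g3")
#' @export
parseGPR <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .gprTokenize(text)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  isKw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parseExpr <- function() {
    args <- list(parseTerm())
    while (isKw(peek(), "or")) { take(); args <- c(args, list(parseTerm())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (isKw(peek(), "and")) { take(); args <- c(args, list(parseFactor())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", text, "'")
    if (t == "(") {
      take()
      e <- parseExpr()
      if (!identical(peek(), ")"))
        stop("GPR parse error: missing ')' in '", text, "'")
      take()
      return(e)
    }
    if (t == ")" || isKw(t, "and") || isKw(t, "or"))
      stop("GPR parse error: unexpected token '", t, "' in '", text, "'")
    take()
    list(op = "gene", gene = t)
  }

  tree <- parseExpr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing token '", peek(), "' in '", text, "'")
  tree
}

#' Evaluate a GPR parse tree under a knockout set
#'
#' @param tree result of \code{\link{parseGPR}} (NULL = no rule, always
#'   active).
#' @param knockouts character vector of knocked-out gene ids.
#' @return TRUE if the reaction remains available.
#' @examples
#' evalGPR(parseGPR("(g1 and g2) or g3"), knockouts = c("g1", "g3"))
#' @export
evalGPR <- function(tree, knockouts = character()) {
  if (is.null(tree)) return(TRUE)
  switch(tree$op,
    gene = !(tree$gene %in% knockouts),
    and = all(vapply(tree$args, evalGPR, logical(1), knockouts = knockouts)),
    or = any(vapply(tree$args, evalGPR, logical(1), knockouts = knockouts)),
    stop("invalid GPR tree node")
  )
}

#' Genes referenced by a GPR parse tree
#'
#' @param tree result of \code{\link{parseGPR}}.
#' @return character vector of unique gene ids (empty for NULL).
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gprGenes)))
}
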
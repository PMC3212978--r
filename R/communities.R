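#' Maximum clique of a binary diversity graph
#'
#' The maximum clique size of a diversity graph is the upper bound of
#' the metabolic diversity that can emerge in the condition: no
#' community of pairwise metabolically different strains can be larger.
#' The search is exact (branch-and-bound via igraph); the returned
#' witness clique is verified pairwise-adjacent and chosen
#' deterministically (lexicographically smallest among the largest
#' cliques).
#'
#' @param bg a binary \linkS4class{DiversityGraph}.
#' @return list with \code{size} (integer; 0 for an empty graph) and
#'   \code{members} (character witness clique).
#' @examples
#' g <- makeFigure1Graph()
#' maxClique(g)$members  # "k" "m" "u"
#' @export
maxClique <- function(bg) {
  stopifnot(bg@binary)
  n <- length(bg@nodes)
  if (n == 0L) return(list(size = 0L, members = character()))
  if (n == 1L) return(list(size = 1L, members = bg@nodes))
  ig <- .asIgraph(bg)
  cls <- igraph::largest_cliques(ig)
  wits <- lapply(cls, function(v) sort(bg@nodes[as.integer(v)]))
  wits <- wits[order(vapply(wits, paste, character(1), collapse = "|"))]
  members <- wits[[1L]]
  A <- bg@weights > 0
  for (a in members) for (b in members)
    if (a != b && !A[a, b])
      stop("internal error: witness clique fails adjacency check")
  list(size = length(members), members = members)
}

#' Enumerate maximal cliques as candidate communities
#'
#' All maximal cliques of size at least \code{minSize}, by exact
#' pivoted enumeration. Every clique is a candidate strain community:
#' a set of strains that are pairwise different in by-production and so
#' have the potential to cross-feed. Output order is deterministic
#' (members sorted within a clique, cliques sorted lexicographically).
#'
#' @param bg a binary \linkS4class{DiversityGraph}.
#' @param minSize smallest community size (default 2).
#' @param maxCount cap on the number of returned communities; when it
#'   truncates, the result carries \code{attr(, "truncated") = TRUE}.
#' @return list of \linkS4class{Community}.
#' @export
enumerateCliques <- function(bg, minSize = 2L, maxCount = Inf) {
  stopifnot(bg@binary)
  if (length(bg@nodes) == 0L) return(structure(list(), truncated = FALSE))
  ig <- .asIgraph(bg)
  cls <- igraph::max_cliques(ig, min = minSize)
  mem <- lapply(cls, function(v) sort(bg@nodes[as.integer(v)]))
  mem <- mem[order(vapply(mem, paste, character(1), collapse = "|"))]
  truncated <- length(mem) > maxCount
  if (truncated) mem <- mem[seq_len(maxCount)]
  out <- lapply(mem, function(m)
    methods::new("Community", members = m,
                 conditionID = bg@conditionID,
                 provenance = list(method = "direct")))
  structure(out, truncated = truncated)
}

#' Find communities through the compressed graph
#'
#' Enumerates maximal cliques on the structurally compressed quotient
#' graph (usually far smaller) and decompresses each by picking one
#' representative per supernode -- deterministically the
#' lexicographically smallest strain id. Because supernode members are
#' identical in by-production, the representative choice cannot affect
#' a subsequent simulation; the provenance records the class sizes so
#' the choice stays reproducible. With \code{expand = TRUE} all
#' representative combinations are produced instead.
#'
#' @param bg a binary \linkS4class{DiversityGraph}.
#' @param minSize smallest community size (default 2).
#' @param expand expand all representative combinations.
#' @param maxCount cap on returned communities (with truncation flag).
#' @return list of \linkS4class{Community}.
#' @export
cliquesViaCompression <- function(bg, minSize = 2L, expand = FALSE,
                                  maxCount = Inf) {
  stopifnot(bg@binary)
  cg <- compressGraph(bg)
  ids <- names(cg@supernodes)
  k <- length(ids)
  if (k == 0L) return(structure(list(), truncated = FALSE))
  qg <- methods::new("DiversityGraph", conditionID = bg@conditionID,
                     nodes = ids,
                     weights = ifelse(cg@quotient, 1, 0) + 0,
                     binary = TRUE, threshold = bg@threshold)
  qCliques <- enumerateCliques(qg, minSize = minSize)
  out <- list()
  truncated <- FALSE
  for (qc in qCliques) {
    classes <- cg@supernodes[qc@members]
    if (expand) {
      combos <- expand.grid(classes, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(combos))) {
        if (length(out) >= maxCount) { truncated <- TRUE; break }
        out[[length(out) + 1L]] <- methods::new("Community",
          members = sort(as.character(unlist(combos[r, ]))),
          conditionID = bg@conditionID,
          provenance = list(method = "compressed-expanded",
                            supernodes = qc@members))
      }
    } else {
      if (length(out) >= maxCount) { truncated <- TRUE; break }
      reps <- vapply(classes, function(m) min(m), character(1))
      out[[length(out) + 1L]] <- methods::new("Community",
        members = sort(unname(reps)), conditionID = bg@conditionID,
        provenance = list(method = "compressed",
                          supernodes = qc@members,
                          classSizes = lengths(classes)))
    }
    if (truncated) break
  }
  ord <- order(vapply(out, function(cm)
    paste(cm@members, collapse = "|"), character(1)))
  structure(out[ord], truncated = truncated)
}
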
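#' Parse an OBO ontology file
#'
#' Reads a flat OBO 1.2/1.4 file and returns the term DAG used to propagate
#' patient phenotype annotations. Only `[Term]` stanzas are interpreted, and
#' within them only the `id`, `name`, `is_a`, `is_obsolete` and `replaced_by`
#' fields; all other relationship types are ignored, so the graph is the
#' plain is_a hierarchy (for HPO, the phenotypic-abnormality tree viewed as a
#' DAG, since terms may have several parents).
#'
#' Obsolete terms are recorded separately with their replacement (when one is
#' given) and never enter the active term set.
#'
#' @param file path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `hpo_ontology`: a list with elements
#'   `terms` (character vector of active term ids), `names` (named character,
#'   term labels), `parents` (named list, is_a parents per term),
#'   `roots` (terms with no parents), and `obsolete` (named character vector
#'   mapping obsolete ids to their replacement or `NA`).
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All",
#'          "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
#'          "is_a: HP:0000001 ! All")
#' onto <- parse_obo(obo)
#' onto$roots
#' @export
parse_obo <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)

  # split into stanzas; only [Term] stanzas matter
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0L) stop("no stanzas found in OBO input")
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- character()
  nms <- character()
  parents <- list()
  obsolete <- character()

  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    if (stanza_starts[s] + 1L > bounds[s + 1L] - 1L) next
    body <- lines[seq(stanza_starts[s] + 1L, bounds[s + 1L] - 1L)]
    body <- body[nzchar(body)]
    field <- sub(":.*$", "", body)
    value <- trimws(sub("^[^:]*:", "", body))

    id <- value[field == "id"][1]
    if (is.na(id)) next
    is_obs <- any(field == "is_obsolete" & tolower(value) == "true")
    if (is_obs) {
      repl <- value[field == "replaced_by"]
      obsolete[id] <- if (length(repl)) repl[1] else NA_character_
      next
    }
    ids <- c(ids, id)
    nm <- value[field == "name"][1]
    nms[id] <- if (is.na(nm)) id else nm
    # strip trailing "! name" comments from is_a targets
    pp <- value[field == "is_a"]
    pp <- trimws(sub("!.*$", "", pp))
    parents[[id]] <- unique(pp[nzchar(pp)])
  }

  if (anyDuplicated(ids)) stop("duplicate term ids in OBO input: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))

  all_parents <- unique(unlist(parents, use.names = FALSE))
  dangling <- setdiff(all_parents, ids)
  if (length(dangling)) {
    stop("is_a parent(s) not defined as terms: ", paste(dangling, collapse = ", "))
  }

  onto <- structure(
    list(terms = ids,
         names = nms,
         parents = parents,
         roots = ids[vapply(parents[ids], length, 1L) == 0L],
         obsolete = obsolete),
    class = "hpo_ontology")
  check_acyclic(onto)
  onto
}

# Kahn topological sort; stops naming one back edge if a cycle exists.
check_acyclic <- function(onto) {
  indeg <- vapply(onto$parents[onto$terms], length, 1L)
  names(indeg) <- onto$terms
  children <- split(
    rep(names(onto$parents), lengths(onto$parents)),
    unlist(onto$parents, use.names = FALSE))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(onto$terms)) {
    bad <- names(indeg)[indeg > 0L][1L]
    stop("cycle detected in is_a graph involving edge ", bad, " is_a ",
         onto$parents[[bad]][1L])
  }
  invisible(onto)
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat("Ontology:", length(x$terms), "active terms,",
      length(x$obsolete), "obsolete,",
      "root(s):", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' Transitive closure over is_a edges, excluding the term itself. Multiple
#' inheritance is handled with set semantics: a term reachable along several
#' paths is returned once.
#'
#' @param onto an `hpo_ontology`.
#' @param term a term id present in `onto$terms`.
#' @return character vector of ancestor term ids (empty for a root).
#' @export
ancestors <- function(onto, term) {
  if (!term %in% onto$terms) stop("unknown term: ", term)
  out <- character()
  frontier <- onto$parents[[term]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(
      unique(unlist(onto$parents[frontier], use.names = FALSE)), out)
  }
  unique(out)
}

# ancestor closure for many terms at once, memoised per call
ancestors_table <- function(onto, terms) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- onto$parents[[t]]
    res <- if (length(ps)) unique(c(ps, unlist(lapply(ps, get_anc), use.names = FALSE)))
           else character()
    memo[[t]] <- res
    res
  }
  stats::setNames(lapply(terms, get_anc), terms)
}

#' Propagate a patient's phenotype terms up the ontology
#'
#' A patient annotated with a term implicitly carries every ancestor of that
#' term. The ontology root(s) are excluded from the propagated set: the root
#' would connect every patient to every other and carries no information.
#' Obsolete terms are mapped through their replacement when one exists and
#' otherwise dropped with a warning.
#'
#' @param onto an `hpo_ontology`.
#' @param direct character vector of asserted term ids (may be empty).
#' @param exclude terms removed from the propagated set; defaults to the
#'   ontology root(s).
#' @return a `term_set`: list with `direct` and `propagated` character vectors.
#' @export
propagate <- function(onto, direct, exclude = onto$roots) {
  direct <- unique(as.character(direct))
  is_obs <- direct %in% names(onto$obsolete)
  if (any(is_obs)) {
    repl <- onto$obsolete[direct[is_obs]]
    dropped <- direct[is_obs][is.na(repl)]
    if (length(dropped)) {
      warning("dropping obsolete term(s) without replacement: ",
              paste(dropped, collapse = ", "))
    }
    direct <- unique(c(direct[!is_obs], repl[!is.na(repl)]))
  }
  unknown <- setdiff(direct, onto$terms)
  if (length(unknown)) stop("unknown term(s): ", paste(unknown, collapse = ", "))
  anc <- ancestors_table(onto, direct)
  prop <- setdiff(unique(c(direct, unlist(anc, use.names = FALSE))), exclude)
  structure(list(direct = setdiff(direct, exclude), propagated = prop),
            class = "term_set")
}

#' Split a term set into most-specific and parental terms
#'
#' A term is parental within a set if some other member of the set descends
#' from it; the rest are the most specific. Case reports mark most-specific
#' terms with "+" and parental terms with "->".
#'
#' @param onto an `hpo_ontology`.
#' @param terms character vector of term ids.
#' @return list with character vectors `specific` and `parental`
#'   (a partition of `terms`).
#' @export
most_specific <- function(onto, terms) {
  terms <- unique(as.character(terms))
  if (!length(terms)) return(list(specific = character(), parental = character()))
  unknown <- setdiff(terms, onto$terms)
  if (length(unknown)) stop("unknown term(s): ", paste(unknown, collapse = ", "))
  anc <- ancestors_table(onto, terms)
  internal_anc <- unique(unlist(anc, use.names = FALSE))
  parental <- intersect(terms, internal_anc)
  list(specific = setdiff(terms, parental), parental = parental)
}
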
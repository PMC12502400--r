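#' Reaction universe: KO -> reaction -> compound mapping
#'
#' The substrate of ortholog retrieval and network construction: which KEGG
#' orthologous gene families (KOs) catalyse which reactions, which compounds
#' sit on each side of each reaction, the text names attached to each
#' compound, and the set of ubiquitous compounds (water, energy carriers,
#' cofactors) excluded from network paths so that paths reflect the main
#' compounds of a reaction.
#'
#' Invariants enforced: every KO maps to at least one reaction; every
#' reaction has at least one compound on reactant or product side; every
#' compound referenced by a reaction carries at least one name; cofactor ids
#' absent from every reaction are accepted with a warning.
#'
#' @param ko_reactions named list: KO id -> character vector of reaction ids.
#' @param reaction_sides named list: reaction id -> list with character
#'   vectors `reactants` and `products`.
#' @param compound_names named list: compound id -> character vector of names.
#' @param cofactors character vector of compound ids treated as ubiquitous.
#' @return a `reaction_universe` object.
#' @export
reaction_universe <- function(ko_reactions, reaction_sides, compound_names,
                              cofactors = character()) {
  ko_reactions <- lapply(ko_reactions, as.character)
  cofactors <- as.character(cofactors)
  n_rxn <- lengths(ko_reactions)
  if (any(n_rxn == 0)) {
    abort(paste0("KO(s) with empty reaction set: ",
                 toString(head(names(ko_reactions)[n_rxn == 0], 5))))
  }
  unknown_rxn <- setdiff(unique(unlist(ko_reactions)), names(reaction_sides))
  if (length(unknown_rxn) > 0) {
    abort(paste0("KO references undefined reaction(s): ", toString(head(unknown_rxn, 5))))
  }
  reaction_sides <- lapply(reaction_sides, function(s) {
    list(reactants = as.character(s$reactants %||% character()),
         products = as.character(s$products %||% character()))
  })
  empty <- vapply(reaction_sides,
                  function(s) length(s$reactants) + length(s$products) == 0L,
                  logical(1))
  if (any(empty)) {
    abort(paste0("reaction(s) with empty reactant and product sets: ",
                 toString(head(names(reaction_sides)[empty], 5))))
  }
  referenced <- unique(unlist(lapply(reaction_sides, unlist), use.names = FALSE))
  unnamed <- referenced[!vapply(referenced, function(cc) {
    nm <- compound_names[[cc]]
    !is.null(nm) && length(nm) > 0
  }, logical(1))]
  if (length(unnamed) > 0) {
    abort(paste0("reaction compound(s) without a name: ", toString(head(unnamed, 5))))
  }
  stray <- setdiff(cofactors, referenced)
  if (length(stray) > 0) {
    warn(paste0("cofactor id(s) not present in any reaction: ", toString(head(stray, 5))))
  }
  structure(
    list(ko_reactions = ko_reactions,
         reaction_sides = reaction_sides,
         compound_names = lapply(compound_names, as.character),
         cofactors = cofactors),
    class = "reaction_universe"
  )
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat(sprintf("<reaction_universe> %d KOs, %d reactions, %d compounds (%d cofactors)\n",
              length(x$ko_reactions), length(x$reaction_sides),
              length(x$compound_names), length(x$cofactors)))
  invisible(x)
}

#' Read / write a reaction universe as JSON
#'
#' The universe is serialized as a single JSON document with keys
#' `ko_reactions`, `reaction_sides`, `compound_names` and `cofactors`. JSON
#' keeps the artifact desk-scale and offline-testable; parsing raw KEGG
#' database dumps is deliberately out of scope.
#'
#' @param path JSON file path.
#' @return [load_reaction_universe()] returns a validated
#'   `reaction_universe`; [write_reaction_universe()] returns `path`
#'   invisibly.
#' @export
load_reaction_universe <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  required <- c("ko_reactions", "reaction_sides", "compound_names", "cofactors")
  missing_keys <- setdiff(required, names(doc))
  if (length(missing_keys) > 0) {
    abort(paste0("reaction universe JSON missing key(s): ", toString(missing_keys)))
  }
  reaction_universe(doc$ko_reactions, doc$reaction_sides, doc$compound_names,
                    doc$cofactors %||% character())
}

#' @rdname load_reaction_universe
#' @param u a `reaction_universe`.
#' @export
write_reaction_universe <- function(u, path) {
  stopifnot(inherits(u, "reaction_universe"))
  doc <- list(ko_reactions = u$ko_reactions,
              reaction_sides = u$reaction_sides,
              compound_names = u$compound_names,
              cofactors = u$cofactors)
  jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = FALSE, digits = NA)
  invisible(path)
}

# All compound ids appearing on any side of a reaction of the universe.
universe_compounds <- function(u) {
  unique(unlist(lapply(u$reaction_sides, unlist), use.names = FALSE))
}
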
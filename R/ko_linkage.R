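#' Find compounds by name pattern
#'
#' Matches a list of case-insensitive regular expressions (unanchored by
#' default, standard POSIX/PCRE-style dialect as interpreted by
#' [stringr::str_detect()]) against every compound name of the universe and
#' returns the ids of compounds with at least one matching name. Matching is
#' performed on names rather than ids because metabolite annotations are
#' retrieved by text. A pattern matching nothing produces a warning, not an
#' error.
#'
#' @param u a `reaction_universe`.
#' @param patterns character vector of regular expressions (>=1).
#' @return character vector of compound ids, with a `match_log` attribute:
#'   a tibble of (pattern, compound, name) for every hit.
#' @export
find_compounds <- function(u, patterns) {
  stopifnot(inherits(u, "reaction_universe"))
  if (length(patterns) < 1) abort("need >=1 pattern")
  name_tbl <- tibble::tibble(
    compound = rep(names(u$compound_names), lengths(u$compound_names)),
    name = unlist(u$compound_names, use.names = FALSE)
  )
  log <- purrr::map_dfr(patterns, function(p) {
    hit <- stringr::str_detect(name_tbl$name, stringr::regex(p, ignore_case = TRUE))
    if (!any(hit)) {
      warn(paste0("pattern matched no compound: '", p, "'"))
      return(tibble::tibble(pattern = character(), compound = character(),
                            name = character()))
    }
    tibble::tibble(pattern = p, compound = name_tbl$compound[hit],
                   name = name_tbl$name[hit])
  })
  ids <- unique(log$compound)
  attr(ids, "match_log") <- log
  ids
}

#' KOs linked to a compound set
#'
#' Returns every KO having at least one reaction whose reactant or product
#' side intersects the given compound set. Reactants and products are
#' treated symmetrically.
#'
#' @param u a `reaction_universe`.
#' @param compounds non-empty character vector of compound ids.
#' @return character vector of KO ids (sorted).
#' @export
kos_for_compounds <- function(u, compounds) {
  stopifnot(inherits(u, "reaction_universe"))
  if (length(compounds) < 1) abort("`compounds` must be non-empty")
  rxn_hits <- names(u$reaction_sides)[vapply(u$reaction_sides, function(s) {
    any(s$reactants %in% compounds) || any(s$products %in% compounds)
  }, logical(1))]
  kos <- names(u$ko_reactions)[vapply(u$ko_reactions, function(r) {
    any(r %in% rxn_hits)
  }, logical(1))]
  sort(kos)
}

#' Glutamate-related KO set
#'
#' When only one metabolome entry is annotated as beta-glutamate, the
#' conventional workaround is to widen the query to all glutamate species:
#' the union of KOs linked to compounds matching the L-, D- and
#' beta-glutamate name patterns. Returns an empty set with a warning when
#' the universe names no glutamate species.
#'
#' @param u a `reaction_universe`.
#' @return character vector of KO ids.
#' @export
glutamate_ko_set <- function(u) {
  ids <- suppressWarnings(
    find_compounds(u, c("L-glutamate", "D-glutamate", "beta-glutamate"))
  )
  if (length(ids) == 0) {
    warn("no glutamate species named in this universe")
    return(character())
  }
  kos_for_compounds(u, ids)
}

#' Link metabolite name patterns to KO ids
#'
#' Convenience wrapper producing the long linkage table used by the
#' pipeline: for each named pattern set, the matched compounds and their
#' linked KOs.
#'
#' @param u a `reaction_universe`.
#' @param pattern_sets named list: metabolite label -> character vector of
#'   name patterns.
#' @return tibble with columns `metabolite`, `compound`, `ko`.
#' @export
link_metabolites_to_kos <- function(u, pattern_sets) {
  stopifnot(inherits(u, "reaction_universe"))
  if (length(pattern_sets) == 0 || is.null(names(pattern_sets))) {
    abort("`pattern_sets` must be a named list of pattern vectors")
  }
  purrr::imap_dfr(pattern_sets, function(pats, label) {
    ids <- suppressWarnings(find_compounds(u, pats))
    if (length(ids) == 0) {
      return(tibble::tibble(metabolite = character(), compound = character(),
                            ko = character()))
    }
    purrr::map_dfr(ids, function(cc) {
      kos <- kos_for_compounds(u, cc)
      if (length(kos) == 0) {
        return(tibble::tibble(metabolite = label, compound = cc, ko = NA_character_))
      }
      tibble::tibble(metabolite = label, compound = cc, ko = kos)
    })
  })
}
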
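# Small fixture builders shared across the suite. Everything is generated in
# code; no data files.

mk_table <- function(values, layer = "taxMG", features = NULL, samples = NULL, ...) {
  values <- as.matrix(values)
  rownames(values) <- features %||% sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  omics_table(values, layer = layer, ...)
}

random_table <- function(n_feat, n_samp, layer = "taxMG", seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_feat * n_samp, 20) + runif(n_feat * n_samp), n_feat)
    mk_table(m, layer = layer)
  })
}

mk_meta <- function(groups, sex = NULL, age = NULL, constipation = NULL) {
  n <- length(groups)
  cohort_metadata(tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    group = groups,
    sex = sex %||% rep(c("M", "F"), length.out = n),
    age = age %||% seq(50, 80, length.out = n),
    constipation = constipation %||% rep(c(TRUE, FALSE), length.out = n),
    cohort = "c1"
  ))
}

# tiny deterministic universe: KO1: A -> B, KO2: B -> C, KO3: D -> E,
# with W a ubiquitous cofactor on every reaction
tiny_universe <- function(cofactors = "W") {
  reaction_universe(
    ko_reactions = list(KO1 = "R1", KO2 = "R2", KO3 = "R3"),
    reaction_sides = list(
      R1 = list(reactants = c("A", "W"), products = "B"),
      R2 = list(reactants = "B", products = c("C", "W")),
      R3 = list(reactants = "D", products = c("E", "W"))
    ),
    compound_names = list(A = "alpha", B = "bravo", C = "charlie",
                          D = "delta", E = "echo", W = "water"),
    cofactors = cofactors
  )
}

random_universe <- function(n_ko = 12, n_compound = 10, n_reaction = 10,
                            seed = 1, cofactors = character()) {
  withr::with_seed(seed, {
    cpds <- sprintf("C%02d", seq_len(n_compound))
    rxns <- sprintf("R%02d", seq_len(n_reaction))
    sides <- lapply(rxns, function(r) {
      k <- sample(2:4, 1)
      side <- sample(cpds, k)
      list(reactants = side[1], products = side[-1])
    })
    names(sides) <- rxns
    kor <- lapply(seq_len(n_ko), function(i) sample(rxns, sample(1:2, 1)))
    names(kor) <- sprintf("K%02d", seq_len(n_ko))
    reaction_universe(kor, sides,
                      setNames(as.list(paste0("name-", cpds)), cpds),
                      cofactors)
  })
}

# tensor fixture: genus x ko x sample array from a seeded Poisson draw
mk_tensor <- function(n_genus = 4, n_ko = 3, n_samp = 6, seed = 1, lambda = 30) {
  withr::with_seed(seed, {
    arr <- array(rpois(n_genus * n_ko * n_samp, lambda),
                 dim = c(n_genus, n_ko, n_samp),
                 dimnames = list(sprintf("g%d", seq_len(n_genus)),
                                 sprintf("K%02d", seq_len(n_ko)),
                                 sprintf("s%02d", seq_len(n_samp))))
    taxon_tensor(arr)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
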
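#' Synthetic reaction universe with a planted hub compound
#'
#' Generates a desk-scale KO -> reaction -> compound universe emulating the
#' structure of a KEGG-derived mapping: random reactions with 1-3 reactants
#' and 1-3 products, ubiquitous cofactors (water, energy carriers) attached
#' to most reactions, and one designated non-cofactor hub compound -- named
#' "L-glutamate" -- participating in a configurable fraction of reactions.
#' Compounds carry text names; designated compounds are named after common
#' gut metabolites (glutamate species, short-chain fatty acids, bile acids)
#' so name-pattern retrieval behaves as it would on real annotations.
#'
#' @param n_ko number of KOs (default 800).
#' @param n_compound number of compounds (default 150).
#' @param n_cofactor number of ubiquitous compounds (default 12).
#' @param hub_degree_fraction fraction of reactions containing the hub
#'   compound, in (0, 1) (default 0.25; the hub-demo preset uses 0.6).
#' @param n_reaction number of reactions (default `round(0.9 * n_ko)`).
#' @param seed integer seed; same seed, same universe.
#' @return list with `universe` (a `reaction_universe`) and `truth` (hub and
#'   glutamate compound ids, cofactors, seed).
#' @export
make_universe <- function(n_ko = 800, n_compound = 150, n_cofactor = 12,
                          hub_degree_fraction = 0.25,
                          n_reaction = round(0.9 * n_ko), seed = 1) {
  if (n_cofactor >= n_compound) abort("`n_cofactor` must be < `n_compound`")
  check_fraction(hub_degree_fraction, "hub_degree_fraction", lo_open = TRUE, hi_open = TRUE)
  if (n_compound < n_cofactor + 20) abort("need >= 20 non-cofactor compounds")

  withr::with_seed(seed, {
    compounds <- sprintf("C%05d", seq_len(n_compound))
    cof_ids <- compounds[seq_len(n_cofactor)]
    free <- setdiff(compounds, cof_ids)

    cof_names <- c("water", "ATP", "ADP", "NAD+", "NADH", "NADP+", "NADPH",
                   "coenzyme A", "orthophosphate", "diphosphate", "H+", "CO2")
    special <- c("L-glutamate", "D-glutamate", "beta-glutamate",
                 "alanine", "serine", "glycerol", "thymine", "glucuronate",
                 "isovalerate", "isobutyrate", "valerate", "butyrate",
                 "acetate", "propionate", "formate",
                 "glycocholate", "chenodeoxycholate", "cholate",
                 "deoxycholate", "malate")
    hub <- free[1]
    named_ids <- free[seq_along(special)]
    compound_names <- as.list(setNames(sprintf("compound-%05d", seq_len(n_compound)),
                                       compounds))
    for (i in seq_len(n_cofactor)) {
      compound_names[[cof_ids[i]]] <- cof_names[((i - 1) %% length(cof_names)) + 1]
    }
    for (i in seq_along(special)) compound_names[[named_ids[i]]] <- special[i]
    # a few compounds carry a synonym, as real annotations do
    syn <- sample(setdiff(free, named_ids), 5)
    for (s in syn) compound_names[[s]] <- c(compound_names[[s]], paste0(s, "-synonym"))

    reactions <- sprintf("R%05d", seq_len(n_reaction))
    reaction_sides <- lapply(seq_len(n_reaction), function(i) {
      nr <- sample(1:3, 1); np <- sample(1:3, 1)
      side <- sample(free, nr + np)
      list(reactants = side[seq_len(nr)], products = side[nr + seq_len(np)])
    })
    names(reaction_sides) <- reactions
    # plant the hub into the designated fraction of reactions
    hub_rxn <- sample(n_reaction, round(hub_degree_fraction * n_reaction))
    for (i in hub_rxn) {
      s <- if (runif(1) < 0.5) "reactants" else "products"
      reaction_sides[[i]][[s]] <- unique(c(reaction_sides[[i]][[s]], hub))
    }
    # cofactors are ubiquitous: attach 1-2 to 80% of reactions, and make
    # sure each cofactor occurs at least once
    for (i in which(runif(n_reaction) < 0.8)) {
      cf <- sample(cof_ids, sample(1:2, 1))
      s <- if (runif(1) < 0.5) "reactants" else "products"
      reaction_sides[[i]][[s]] <- unique(c(reaction_sides[[i]][[s]], cf))
    }
    used <- unique(unlist(lapply(reaction_sides, unlist), use.names = FALSE))
    for (cf in setdiff(cof_ids, used)) {
      i <- sample(n_reaction, 1)
      reaction_sides[[i]]$reactants <- unique(c(reaction_sides[[i]]$reactants, cf))
    }

    kos <- sprintf("K1%04d", seq_len(n_ko))
    panel <- unname(flagellar_gene_panel())
    kos[seq_along(panel)] <- panel
    ko_reactions <- lapply(seq_len(n_ko), function(i) {
      sample(reactions, sample(1:3, 1))
    })
    names(ko_reactions) <- kos

    u <- reaction_universe(ko_reactions, reaction_sides, compound_names, cof_ids)
    glut <- named_ids[1:3]
    list(universe = u,
         truth = list(hub_compound = hub, glutamate_compounds = glut,
                      cofactors = cof_ids, flagellar_kos = flagellar_gene_panel(),
                      seed = seed))
  })
}

#' Synthetic cohort metadata
#'
#' Three diagnosis groups with the structural features of a prodromal
#' Parkinson's cohort: male excess and higher constipation prevalence in the
#' iRBD and PD groups, ages from one shared distribution, and two
#' recruitment cohorts. Defaults mirror the 49 HC / 27 iRBD / 46 PD design.
#'
#' @param n_hc,n_irbd,n_pd group sizes (each >= 3).
#' @param seed integer seed.
#' @return a `cohort_metadata` tibble.
#' @export
make_cohort <- function(n_hc = 49, n_irbd = 27, n_pd = 46, seed = 1) {
  if (min(n_hc, n_irbd, n_pd) < 3) abort("each group needs n >= 3")
  withr::with_seed(seed, {
    n <- n_hc + n_irbd + n_pd
    group <- rep(c("HC", "iRBD", "PD"), c(n_hc, n_irbd, n_pd))
    p_male <- c(HC = 0.50, iRBD = 0.80, PD = 0.65)[group]
    p_consti <- c(HC = 0.12, iRBD = 0.30, PD = 0.33)[group]
    cohort_metadata(tibble::tibble(
      sample = sprintf("S%03d", seq_len(n)),
      group = group,
      sex = ifelse(runif(n) < p_male, "M", "F"),
      age = round(pmin(pmax(rnorm(n, 65, 8), 40), 85), 1),
      constipation = runif(n) < p_consti,
      cohort = sample(c("cohortA", "cohortB"), n, replace = TRUE)
    ))
  })
}

#' Effect configuration for the synthetic study
#'
#' Bundles the planted-effect sizes and dimensions of the generator. The
#' defaults define the package's reference study conditions: overdispersed
#' gamma-Poisson counts (shape 3) with log-normal sequencing depths,
#' 4-fold planted metabolite shifts in PD with a square-root-attenuated
#' intermediate effect in iRBD, a 4-fold transcript-only decrease in PD
#' (fold 0.25) for a planted KO set that leaves gene abundances untouched,
#' 3-fold sex leakage into 15% of taxMT/funMT features, and 5-fold
#' suppression of extracellular flagellar genes in PD for two genera.
#'
#' @param n_taxa,n_genera,n_tensor_ko,mm_untargeted,mm_scfa,mm_bile
#'   feature-space dimensions.
#' @param n_mm_diff,mm_fold planted differential metabolites and their fold.
#' @param n_transcript_ko,transcript_fold transcript-only KO set and its PD
#'   multiplier (< 1 means decreased expression).
#' @param sex_fraction,sex_fold confounder leakage into taxMT/funMT.
#' @param n_unidentified unidentified (unlinkable) untargeted compounds.
#' @param suppressed_genera,suppression_fold flagellar suppression planting.
#' @param depth_taxa,depth_fun,depth_mp,depth_sdlog sequencing depth model.
#' @param dispersion_shape gamma shape of the overdispersion mixture.
#' @param mm_sdlog log-scale noise of metabolite intensities.
#' @param mm_planted_intensity baseline-intensity multiplier for planted
#'   differential metabolites (default 1/12): differential compounds are
#'   minor constituents, keeping the metabolome's community-level group
#'   separation at the modest scale typical of fecal metabolomes while
#'   rank-based per-feature tests keep full power.
#' @return a named list of class `effect_config`.
#' @export
effect_config <- function(n_taxa = 300, n_genera = 40, n_tensor_ko = 120,
                          mm_untargeted = 180, mm_scfa = 8, mm_bile = 12,
                          n_mm_diff = 20, mm_fold = 4,
                          n_transcript_ko = 30, transcript_fold = 0.25,
                          sex_fraction = 0.15, sex_fold = 3,
                          n_unidentified = 30,
                          suppressed_genera = 2, suppression_fold = 0.2,
                          depth_taxa = 2e4, depth_fun = 2e5, depth_mp = 1e4,
                          depth_sdlog = 0.3, dispersion_shape = 3,
                          mm_sdlog = 0.6, mm_planted_intensity = 1 / 12) {
  structure(as.list(environment()), class = "effect_config")
}

#' @rdname effect_config
#' @export
null_effect_config <- function(...) {
  cfg <- effect_config(...)
  cfg$n_mm_diff <- 0L
  cfg$n_transcript_ko <- 0L
  cfg$sex_fraction <- 0
  cfg$suppressed_genera <- 0L
  cfg
}

# gamma-Poisson counts: lambda = base %o% depth * mult, overdispersed per cell
sim_counts <- function(base, depth, mult = NULL, shape = 3) {
  lambda <- outer(base, depth)
  if (!is.null(mult)) lambda <- lambda * mult
  noisy <- lambda * matrix(rgamma(length(lambda), shape, shape), nrow(lambda))
  matrix(rpois(length(noisy), noisy), nrow(lambda), dimnames = dimnames(lambda))
}

# multiplicative group/sex effect matrix for a feature x sample block
effect_matrix <- function(features, meta, planted, fold, by = c("group", "sex")) {
  by <- match.arg(by)
  mult <- matrix(1, length(features), nrow(meta),
                 dimnames = list(features, meta$sample))
  if (length(planted) == 0) return(mult)
  if (by == "group") {
    mult[planted, meta$group == "PD"] <- fold
    mult[planted, meta$group == "iRBD"] <- sqrt(fold)
  } else {
    mult[planted, meta$sex == "M" & !is.na(meta$sex)] <- fold
  }
  mult
}

#' Generate the full synthetic multi-omics study
#'
#' Produces all seven omics layers, the genus x KO x sample expression
#' tensor, and the recorded planted truth, all consistent with one another:
#' MM metabolite shifts are planted in PD (with an attenuated iRBD effect)
#' including a beta-glutamate increase and primary-bile-acid decreases;
#' a KO set is modulated in funMT only, leaving funMG untouched
#' (transcript-only dissociation); sex leakage is injected into taxMT and
#' funMT only, so guide-layer selection must reject them; collapsing the
#' tensor over genera reproduces the funMT rows of the tensor's KOs exactly;
#' extracellular flagellar genes of designated genera are suppressed in PD.
#'
#' @param u a `reaction_universe` (from [make_universe()]).
#' @param meta a `cohort_metadata` tibble (from [make_cohort()]).
#' @param effects an [effect_config()].
#' @param seed integer master seed; each layer draws from a derived
#'   substream.
#' @return list with `layers` (named list of raw `omics_table`s:
#'   taxMG/taxMT/taxMP/funMG/funMT/funMP and the merged `MM`), `mm_blocks`
#'   (the three unmerged blocks), `tensor` (count `taxon_tensor`), and
#'   `truth` (planted truth, serializable with [write_planted_truth()]).
#' @export
make_multiomics <- function(u, meta, effects = effect_config(), seed = 1) {
  stopifnot(inherits(u, "reaction_universe"), inherits(meta, "cohort_metadata"))
  cfg <- effects
  n_s <- nrow(meta)
  samples <- meta$sample
  kos <- names(u$ko_reactions)
  n_ko <- length(kos)
  shape <- cfg$dispersion_shape

  # --- planted sets -------------------------------------------------------
  plant <- withr::with_seed(sub_seed(seed, 1), {
    taxa <- sprintf("t%04d", seq_len(cfg$n_taxa))
    genera <- sprintf("g%03d", seq_len(cfg$n_genera))
    panel <- unname(flagellar_gene_panel())
    samp <- function(x, size) sample(x, min(max(size, 0), length(x)))
    tensor_kos <- unique(c(intersect(panel, kos),
                           samp(setdiff(kos, panel),
                                cfg$n_tensor_ko - length(intersect(panel, kos)))))
    transcript_kos <- if (cfg$n_transcript_ko > 0) {
      samp(kos, cfg$n_transcript_ko)
    } else character()
    sex_tax <- if (cfg$sex_fraction > 0) {
      samp(taxa, round(cfg$sex_fraction * cfg$n_taxa))
    } else character()
    sex_fun <- if (cfg$sex_fraction > 0) {
      samp(setdiff(kos, transcript_kos), round(cfg$sex_fraction * n_ko))
    } else character()
    sup_genera <- if (cfg$suppressed_genera > 0) genera[seq_len(cfg$suppressed_genera)] else character()
    list(taxa = taxa, genera = genera, tensor_kos = tensor_kos,
         transcript_kos = transcript_kos, sex_tax = sex_tax, sex_fun = sex_fun,
         suppressed = tidyr::expand_grid(genus = sup_genera,
                                         ko = intersect(panel, kos)))
  })

  # --- taxonomic layers ---------------------------------------------------
  tax_layer <- function(layer, s_off, mean_depth, sex_feats = character()) {
    withr::with_seed(sub_seed(seed, s_off), {
      base <- exp(rnorm(cfg$n_taxa, 0, 1.5)); base <- base / sum(base)
      names(base) <- plant$taxa
      d <- rlnorm(n_s, log(mean_depth), cfg$depth_sdlog)
      mult <- effect_matrix(plant$taxa, meta, sex_feats, cfg$sex_fold, by = "sex")
      vals <- sim_counts(base, setNames(d, samples), mult, shape)
      omics_table(vals, layer = layer, normalized = FALSE)
    })
  }
  taxMG <- tax_layer("taxMG", 10, cfg$depth_taxa)
  taxMT <- tax_layer("taxMT", 11, cfg$depth_taxa, sex_feats = plant$sex_tax)
  taxMP <- tax_layer("taxMP", 12, cfg$depth_mp)

  # --- functional layers --------------------------------------------------
  funres <- withr::with_seed(sub_seed(seed, 20), {
    base <- exp(rnorm(n_ko, 0, 1.5)); base <- base / sum(base)
    names(base) <- kos
    d_mg <- rlnorm(n_s, log(cfg$depth_fun), cfg$depth_sdlog)
    mg <- sim_counts(base, setNames(d_mg, samples), NULL, shape)

    activity <- setNames(rlnorm(n_ko, 0, 0.5), kos)
    d_mt <- rlnorm(n_s, log(cfg$depth_fun), cfg$depth_sdlog)
    mult <- effect_matrix(kos, meta, plant$transcript_kos, cfg$transcript_fold,
                          by = "group") *
      effect_matrix(kos, meta, plant$sex_fun, cfg$sex_fold, by = "sex")
    lambda_mt <- outer(base * activity, setNames(d_mt, samples)) * mult
    lambda_mt <- lambda_mt * matrix(rgamma(length(lambda_mt), shape, shape),
                                    nrow(lambda_mt))

    # tensor KOs: split expression across genera, then Poisson per cell
    n_g <- cfg$n_genera
    loadings <- vapply(plant$tensor_kos, function(k) {
      w <- rgamma(n_g, 1, 1) * (runif(n_g) < 0.3)
      if (sum(w) == 0) w[sample(n_g, 1)] <- 1
      w / sum(w)
    }, numeric(n_g))            # genera x tensor_kos
    rownames(loadings) <- plant$genera
    tensor <- array(0, dim = c(n_g, length(plant$tensor_kos), n_s),
                    dimnames = list(plant$genera, plant$tensor_kos, samples))
    for (j in seq_along(plant$tensor_kos)) {
      k <- plant$tensor_kos[j]
      cell_lambda <- outer(loadings[, j], lambda_mt[k, ])
      if (nrow(plant$suppressed) > 0 && k %in% plant$suppressed$ko) {
        sg <- plant$suppressed$genus[plant$suppressed$ko == k]
        cell_lambda[sg, meta$group == "PD"] <-
          cell_lambda[sg, meta$group == "PD"] * cfg$suppression_fold
      }
      tensor[, j, ] <- matrix(rpois(length(cell_lambda), cell_lambda), n_g)
    }
    mt <- matrix(rpois(length(lambda_mt), lambda_mt), n_ko,
                 dimnames = dimnames(lambda_mt))
    # funMT rows of tensor KOs are the genus-collapsed tensor, exactly
    mt[plant$tensor_kos, ] <- apply(tensor, c(2, 3), sum)

    d_mp <- rlnorm(n_s, log(cfg$depth_mp), cfg$depth_sdlog)
    mp <- sim_counts(base, setNames(d_mp, samples), NULL, shape)
    list(mg = mg, mt = mt, mp = mp, tensor = tensor)
  })
  funMG <- omics_table(funres$mg, "funMG")
  funMT <- omics_table(funres$mt, "funMT")
  funMP <- omics_table(funres$mp, "funMP")
  tensor <- taxon_tensor(funres$tensor, tpm = FALSE,
                         genus_info = tibble::tibble(
                           genus = plant$genera,
                           family = paste0("f", rep(seq_len(8), length.out = cfg$n_genera))))

  # --- meta-metabolome ----------------------------------------------------
  mm <- withr::with_seed(sub_seed(seed, 30), {
    cof_names <- unlist(u$compound_names[u$cofactors], use.names = FALSE)
    targeted <- c("isovalerate", "isobutyrate", "valerate", "butyrate",
                  "acetate", "propionate", "formate",
                  "glycocholate", "chenodeoxycholate", "cholate", "deoxycholate")
    pool <- setdiff(unique(unlist(u$compound_names[universe_compounds(u)],
                                  use.names = FALSE)),
                    c(cof_names, targeted))
    n_ident <- cfg$mm_untargeted - cfg$n_unidentified
    ident_names <- c(head(pool, min(length(pool), n_ident)))
    if (length(ident_names) < n_ident) {
      ident_names <- c(ident_names,
                       sprintf("metab_%03d", seq_len(n_ident - length(ident_names))))
    }
    unident <- sprintf("unknown_%03d", seq_len(cfg$n_unidentified))

    scfa_feats <- c("acetate", "propionate", "butyrate", "formate",
                    "isovalerate", "isobutyrate", "valerate", "total_SCFA")[seq_len(cfg$mm_scfa)]
    bile_feats <- c("glycocholate", "chenodeoxycholate", "cholate",
                    "deoxycholate", "taurocholate", "lithocholate",
                    sprintf("bile_acid_%02d", seq_len(6)))[seq_len(cfg$mm_bile)]

    # planted differential compounds, mirroring the qualitative directions:
    # beta-glutamate and branched SCFAs up in PD, primary bile acids down
    planted <- tibble::tibble(feature = character(), direction = numeric())
    if (cfg$n_mm_diff > 0) {
      fixed <- tibble::tibble(
        feature = c("beta-glutamate", "isovalerate", "isobutyrate", "valerate",
                    "glycocholate", "chenodeoxycholate"),
        direction = c(1, 1, 1, 1, -1, -1))
      fixed <- dplyr::filter(fixed, .data$feature %in% c(ident_names, scfa_feats, bile_feats))
      n_extra <- max(cfg$n_mm_diff - nrow(fixed), 0)
      extra_pool <- setdiff(ident_names, fixed$feature)
      extra <- head(sample(extra_pool), n_extra)
      planted <- dplyr::bind_rows(fixed, tibble::tibble(
        feature = extra,
        direction = rep_len(c(1, -1), length(extra))))
      planted <- head(planted, cfg$n_mm_diff)
    }

    mm_block <- function(feats) {
      meanlog <- rnorm(length(feats), 0, 1)
      # planted differential metabolites are minor compounds: their baseline
      # intensity is scaled down so the community-level group separation
      # (PERMANOVA R^2) sits at the modest scale reported for real fecal
      # metabolomes, while rank-based per-feature tests keep full power
      meanlog[feats %in% planted$feature] <-
        meanlog[feats %in% planted$feature] + log(cfg$mm_planted_intensity)
      mult <- matrix(1, length(feats), n_s, dimnames = list(feats, samples))
      hit <- intersect(feats, planted$feature)
      for (f in hit) {
        dirn <- planted$direction[planted$feature == f]
        fold <- cfg$mm_fold^dirn
        mult[f, meta$group == "PD"] <- fold
        mult[f, meta$group == "iRBD"] <- sqrt(fold)
      }
      vals <- exp(matrix(rnorm(length(feats) * n_s, meanlog, cfg$mm_sdlog),
                         length(feats), dimnames = list(feats, samples))) * mult
      vals
    }
    untar_feats <- c(ident_names, unident)
    untargeted <- omics_table(mm_block(untar_feats), "MM", feature_info = tibble::tibble(
      feature = untar_feats, identified = untar_feats %in% ident_names))
    scfa <- omics_table(mm_block(scfa_feats), "MM", feature_info = tibble::tibble(
      feature = scfa_feats, identified = TRUE))
    bile <- omics_table(mm_block(bile_feats), "MM", feature_info = tibble::tibble(
      feature = bile_feats, identified = TRUE))
    list(untargeted = untargeted, scfa = scfa, bile_acids = bile,
         planted = planted, unidentified = unident)
  })
  MM <- merge_mm_blocks(mm$untargeted, mm$scfa, mm$bile_acids)

  truth <- list(
    mm_diff = dplyr::mutate(mm$planted, fold = cfg$mm_fold),
    unidentified = mm$unidentified,
    transcript_kos = plant$transcript_kos,
    transcript_fold = cfg$transcript_fold,
    confounded_layers = if (cfg$sex_fraction > 0) c("taxMT", "funMT") else character(),
    sex_features = list(taxMT = plant$sex_tax, funMT = plant$sex_fun),
    tensor_kos = plant$tensor_kos,
    suppressed_pairs = plant$suppressed,
    flagellar_kos = flagellar_gene_panel(),
    seed = seed,
    config = unclass(cfg)
  )

  list(
    layers = list(taxMG = taxMG, taxMT = taxMT, taxMP = taxMP,
                  funMG = funMG, funMT = funMT, funMP = funMP, MM = MM),
    mm_blocks = list(untargeted = mm$untargeted, scfa = mm$scfa,
                     bile_acids = mm$bile_acids),
    tensor = tensor,
    truth = truth
  )
}

#' Generate a complete synthetic study from a preset
#'
#' Presets: `"paper-like"` (all planted effects at their default sizes),
#' `"null"` (no planted effects anywhere -- every layer exchangeable across
#' groups), `"hub-demo"` (paper-like effects plus a strongly dominant hub
#' compound, hub degree fraction 0.6). Optionally writes every file the
#' pipeline reads, plus `planted_truth.json`.
#'
#' @param preset one of `"paper-like"`, `"null"`, `"hub-demo"`.
#' @param seed master seed.
#' @param dims optional named list overriding generator dimensions: any
#'   [effect_config()] argument, plus `n_ko`, `n_compound`, `n_cofactor`,
#'   `n_hc`, `n_irbd`, `n_pd`.
#' @param out_dir optional output directory.
#' @return list with `universe`, `meta`, `layers`, `mm_blocks`, `tensor`,
#'   `truth`, `preset`, `files` (when written).
#' @export
generate_study <- function(preset = c("paper-like", "null", "hub-demo"),
                           seed = 1, dims = list(), out_dir = NULL) {
  preset <- match.arg(preset)
  uni_args <- dims[intersect(names(dims), c("n_ko", "n_compound", "n_cofactor", "n_reaction"))]
  uni_args$hub_degree_fraction <- dims$hub_degree_fraction %||%
    if (preset == "hub-demo") 0.6 else 0.25
  uni_args$seed <- sub_seed(seed, 101)
  uni <- do.call(make_universe, uni_args)

  meta <- make_cohort(n_hc = dims$n_hc %||% 49, n_irbd = dims$n_irbd %||% 27,
                      n_pd = dims$n_pd %||% 46, seed = sub_seed(seed, 102))

  cfg_fun <- if (preset == "null") null_effect_config else effect_config
  cfg_args <- dims[intersect(names(dims), names(formals(effect_config)))]
  cfg <- do.call(cfg_fun, cfg_args)
  omics <- make_multiomics(uni$universe, meta, effects = cfg,
                           seed = sub_seed(seed, 103))

  truth <- c(omics$truth, uni$truth[c("hub_compound", "glutamate_compounds")])
  study <- list(universe = uni$universe, meta = meta, layers = omics$layers,
                mm_blocks = omics$mm_blocks, tensor = omics$tensor,
                truth = truth, preset = preset, seed = seed)
  if (!is.null(out_dir)) study$files <- write_study(study, out_dir)
  study
}

#' Write a synthetic study to disk
#'
#' Writes the per-layer TSV tables (the three unmerged metabolome blocks,
#' not the merged table), the metadata TSV, the reaction universe JSON, the
#' tensor long TSV and `planted_truth.json`.
#'
#' @param study result of [generate_study()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  files <- c()
  for (nm in setdiff(names(study$layers), "MM")) {
    files[nm] <- p(paste0(nm, ".tsv"))
    write_omics_table(study$layers[[nm]], files[nm])
  }
  for (nm in names(study$mm_blocks)) {
    files[paste0("mm_", nm)] <- p(paste0("mm_", nm, ".tsv"))
    write_omics_table(study$mm_blocks[[nm]], files[paste0("mm_", nm)])
  }
  files["metadata"] <- p("metadata.tsv")
  write_metadata(study$meta, files["metadata"])
  files["universe"] <- p("reaction_universe.json")
  write_reaction_universe(study$universe, files["universe"])
  files["tensor"] <- p("tensor.tsv")
  write_taxon_tensor(study$tensor, files["tensor"])
  files["planted_truth"] <- p("planted_truth.json")
  write_planted_truth(study$truth, files["planted_truth"])
  invisible(files)
}

#' @rdname write_study
#' @param truth planted-truth list.
#' @param path JSON path.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
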
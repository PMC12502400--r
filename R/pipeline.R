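#' Load a study from a directory of pipeline input files
#'
#' Reads the layer TSVs, the three metabolome blocks (merged on load), the
#' metadata TSV, the reaction universe JSON and the expression tensor, as
#' written by [write_study()].
#'
#' @param dir directory containing the input files.
#' @return a study list (`universe`, `meta`, `layers`, `mm_blocks`,
#'   `tensor`).
#' @export
load_study <- function(dir) {
  p <- function(...) file.path(dir, ...)
  layer_names <- c("taxMG", "taxMT", "taxMP", "funMG", "funMT", "funMP")
  layers <- lapply(setNames(layer_names, layer_names), function(nm) {
    load_omics_table(p(paste0(nm, ".tsv")), layer = nm)
  })
  mm_blocks <- list(
    untargeted = load_omics_table(p("mm_untargeted.tsv"), "MM"),
    scfa = load_omics_table(p("mm_scfa.tsv"), "MM"),
    bile_acids = load_omics_table(p("mm_bile_acids.tsv"), "MM")
  )
  # unidentified compounds are recognizable by their feature ids
  mm_blocks$untargeted$feature_info <- tibble::tibble(
    feature = rownames(mm_blocks$untargeted$values),
    identified = !startsWith(rownames(mm_blocks$untargeted$values), "unknown"))
  layers$MM <- merge_mm_blocks(mm_blocks$untargeted, mm_blocks$scfa,
                               mm_blocks$bile_acids)
  list(universe = load_reaction_universe(p("reaction_universe.json")),
       meta = load_metadata(p("metadata.tsv")),
       layers = layers, mm_blocks = mm_blocks,
       tensor = load_taxon_tensor(p("tensor.tsv")))
}

#' Default pipeline configuration
#'
#' @param input_dir directory of input files (alternative to `study`).
#' @param study in-memory study list (e.g. from [generate_study()]).
#' @param out output directory for stage files and the run report.
#' @param seed master seed for every permutation stream.
#' @param alpha PERMANOVA screening threshold (default 0.05).
#' @param q_threshold FDR threshold for feature-level significance
#'   (default 0.05).
#' @param n_perm PERMANOVA permutations (default 1000).
#' @param prevalence KO prevalence filter for the network (default 0.5).
#' @param confounders metadata columns screened in guide-layer selection.
#' @param pair group pair driving fold changes (default HC vs PD).
#' @param patterns optional named list of metabolite-name pattern sets for
#'   KO linkage; by default the significant compound names themselves are
#'   used, with any glutamate species widened to the L-/D-/beta-glutamate
#'   trio.
#' @param pathways named list of pathway KO vectors (default: the
#'   extracellular flagellar panel).
#' @param cluster_k genus cluster count (default 4).
#' @return a config list for [run_all()].
#' @export
pipeline_config <- function(input_dir = NULL, study = NULL, out = tempfile("run"),
                            seed = 1, alpha = 0.05, q_threshold = 0.05,
                            n_perm = 1000, prevalence = 0.5,
                            confounders = c("sex", "age", "constipation"),
                            pair = c("HC", "PD"), patterns = NULL,
                            pathways = list(flagellar_extracellular = flagellar_gene_panel()),
                            cluster_k = 4) {
  if (is.null(input_dir) && is.null(study)) {
    abort("config needs `input_dir` or `study`")
  }
  as.list(environment())
}

#' Run the full metabolome-guided analysis chain
#'
#' Executes the stages in order -- guide-layer selection, metabolite
#' differential testing, KO linkage, gene-vs-transcript differential
#' analysis, taxon-resolved expression, community network -- writing every
#' stage's TSV/GraphML output plus a machine-readable JSON run report of
#' parameters, seeds and headline results. Stages communicate through the
#' returned state and their files; any stage contract violation aborts with
#' the stage name while earlier outputs are retained alongside a failure
#' marker. When no guide layer is eligible, or no compound is significant,
#' the dependent stages are skipped gracefully and the report says so.
#'
#' Re-running with the same config and seed reproduces every output file
#' byte for byte.
#'
#' @param config list from [pipeline_config()], or a path to a YAML/JSON
#'   file with the same fields.
#' @param stages subset of stages to run (dependencies are not re-run; the
#'   default runs everything).
#' @return the run report (list), invisibly readable from
#'   `<out>/run_report.json`.
#' @export
run_all <- function(config, stages = c("ecology", "metabolites", "link-kos",
                                       "functional", "taxa", "network")) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out, ...)

  study <- config$study %||% load_study(config$input_dir)
  meta <- study$meta
  report <- list(
    parameters = config[c("seed", "alpha", "q_threshold", "n_perm",
                          "prevalence", "confounders", "pair", "cluster_k")],
    stages = list()
  )
  state <- list()

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- Sys.time()
    message("[", name, "] starting")
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 p("FAILED"))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # --- ecology: alpha diversity + guide-layer selection -------------------
  run_stage("ecology", function() {
    alpha_tbl <- purrr::map_dfr(study$layers, sample_shannon)
    readr::write_tsv(alpha_tbl, p("alpha_diversity.tsv"), progress = FALSE)
    sel <- select_guide_layer(
      study$layers, meta,
      confounders = config$confounders %||% c("sex", "age", "constipation"),
      alpha = config$alpha, n_perm = config$n_perm, seed = config$seed)
    readr::write_tsv(tidy(sel), p("guide_selection.tsv"), progress = FALSE)
    readr::write_tsv(sel$verdict, p("guide_verdict.tsv"), progress = FALSE)
    state$selection <<- sel
    report$stages$ecology <<- list(winner = sel$winner, eligible = sel$eligible)
  })

  guided <- identical(state$selection$winner %||% "MM", "MM")
  if (!guided) {
    report$stages$note <- "no eligible MM guide layer; downstream stages skipped"
  }

  # --- metabolites: guide-layer differential testing ----------------------
  run_stage("metabolites", function() {
    if (!guided) return(invisible(NULL))
    mm <- study$layers$MM
    identified <- if (!is.null(mm$feature_info) && "identified" %in% names(mm$feature_info)) {
      mm$feature_info$feature[!isFALSE(mm$feature_info$identified) &
                                !is.na(mm$feature_info$identified) &
                                mm$feature_info$identified]
    } else rownames(mm$values)
    mm_id <- omics_table(mm$values[identified, , drop = FALSE], "MM",
                         feature_info = mm$feature_info[
                           match(identified, mm$feature_info$feature), ])
    diff <- kruskal_dunn(mm_id, meta)
    write_diff_table(diff, p("mm_differential.tsv"))
    sig <- significant_compounds(diff, config$q_threshold)
    readr::write_tsv(sig, p("significant_compounds.tsv"), progress = FALSE)
    state$mm_sig <<- sig
    report$stages$metabolites <<- list(n_tested = length(identified),
                                       n_significant = nrow(sig),
                                       compounds = sig$feature)
  })

  have_sig <- !is.null(state$mm_sig) && nrow(state$mm_sig) > 0
  if ("metabolites" %in% stages && guided && !have_sig) {
    report$stages$note <- "zero significant compounds; linkage and functional stages skipped"
  }

  # --- link-kos: metabolite -> compound -> KO -----------------------------
  run_stage("link-kos", function() {
    if (!guided || !have_sig) return(invisible(NULL))
    pats <- config$patterns %||% default_patterns(state$mm_sig$feature)
    link <- link_metabolites_to_kos(study$universe, pats)
    readr::write_tsv(link, p("linked_kos.tsv"), progress = FALSE)
    state$linked <<- link
    kos <- sort(unique(link$ko[!is.na(link$ko)]))
    state$kos <<- kos
    report$stages$link_kos <<- list(n_patterns = length(pats),
                                    n_compounds = dplyr::n_distinct(link$compound),
                                    n_kos = length(kos))
  })

  # --- functional: genes vs transcripts over the linked KOs ---------------
  run_stage("functional", function() {
    if (!guided || !have_sig || length(state$kos %||% character()) == 0) {
      return(invisible(NULL))
    }
    mg_n <- sum_normalize(study$layers$funMG)
    mt_n <- sum_normalize(study$layers$funMT)
    diff <- differential_ko(mg_n, mt_n, meta, state$kos, config$pair)
    write_diff_table(diff, p("ko_differential.tsv"))
    corr <- metabolite_feature_correlation(
      study$layers$MM, sum_normalize(study$layers$taxMT),
      mm_features = state$mm_sig$feature)
    write_diff_table(corr, p("metabolite_taxmt_correlation.tsv"))
    panels <- purrr::imap(config$pathways %||% list(), function(kos, nm) {
      pp <- pathway_panel(mg_n, mt_n, study$tensor, meta, kos, config$pair,
                          config$q_threshold)
      write_diff_table(tidy(pp), p(paste0("pathway_", nm, ".tsv")))
      pp$tally
    })
    state$ko_diff <<- diff
    report$stages$functional <<- list(
      n_kos = length(state$kos),
      n_sig_funMT = sum(diff$layer == "funMT" & diff$q < config$q_threshold, na.rm = TRUE),
      n_sig_funMG = sum(diff$layer == "funMG" & diff$q < config$q_threshold, na.rm = TRUE),
      pathway_tallies = panels)
  })

  # --- taxa: genus-resolved expression ------------------------------------
  run_stage("taxa", function() {
    tpm <- tpm_normalize(study$tensor)
    prof <- genus_group_profiles(tpm, meta)
    readr::write_tsv(prof$cells, p("genus_ko_group_tpm.tsv"), progress = FALSE)
    readr::write_tsv(prof$genus_totals, p("genus_group_totals.tsv"), progress = FALSE)
    cl <- cluster_genera(prof, pair = config$pair, k = config$cluster_k)
    readr::write_tsv(cl, p("genus_clusters.tsv"), progress = FALSE)
    flag <- extracellular_flagellar_report(tpm, meta,
                                           genera = dimnames(tpm$values)[[1]])
    write_diff_table(flag, p("flagellar_report.tsv"))
    state$clusters <<- cl
    report$stages$taxa <<- list(
      n_genera = dplyr::n_distinct(cl$genus), k = config$cluster_k,
      n_flagellar_sig = sum(flag$comparison == "omnibus" &
                              flag$q < config$q_threshold, na.rm = TRUE))
  })

  # --- network: community-wide KO-metabolite graph ------------------------
  run_stage("network", function() {
    net <- build_network(study$universe, study$layers$funMG,
                         prevalence = config$prevalence)
    net <- attach_activity(net, sum_normalize(study$layers$funMT),
                           sum_normalize(study$layers$funMG))
    g_ko <- project_ko(net)
    g_cpd <- project_compound(net)
    bc_ko <- betweenness_centrality(g_ko)
    bc_cpd <- betweenness_centrality(g_cpd)
    readr::write_tsv(bc_ko, p("bc_ko.tsv"), progress = FALSE)
    readr::write_tsv(bc_cpd, p("bc_compound.tsv"), progress = FALSE)
    readr::write_tsv(net$activity, p("ko_activity.tsv"), progress = FALSE)
    write_network_graphml(g_ko, p("network_ko.graphml"))
    write_network_graphml(g_cpd, p("network_compound.graphml"))
    subs <- list(glutamate = intersect(glutamate_ko_set(study$universe), bc_ko$node))
    if (length(state$kos %||% character()) > 0) {
      subs$mm_linked <- intersect(state$kos, bc_ko$node)
    }
    sub_tbl <- purrr::imap_dfr(subs, function(nodes, nm) {
      if (length(nodes) == 0) return(tibble::tibble())
      subnetwork_report(g_ko, bc_ko, nodes, label = nm)
    })
    readr::write_tsv(sub_tbl, p("subnetworks.tsv"), progress = FALSE)
    top_cpd <- bc_cpd$node[order(-bc_cpd$bc_raw)][1]
    report$stages$network <<- list(
      n_ko_nodes = length(net$kos), n_compound_nodes = length(net$compounds),
      top_compound = top_cpd,
      top_compound_names = unlist(study$universe$compound_names[top_cpd]),
      subnetworks = sub_tbl)
  })

  jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

# Build pattern sets from significant compound names: fixed-string matching
# on each name, with any glutamate species widened to the L-/D-/beta trio
# (only one metabolome entry is typically annotated as beta-glutamate, so
# all glutamate-related genes are retrieved instead).
default_patterns <- function(features) {
  pats <- lapply(features, function(f) {
    if (grepl("glutamate", f, ignore.case = TRUE)) {
      c("L-glutamate", "D-glutamate", "beta-glutamate")
    } else {
      paste0("^", escape_regex(f), "$")
    }
  })
  names(pats) <- features
  pats
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
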
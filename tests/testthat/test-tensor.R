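test_that("tensor long-TSV round trip is lossless", {
  tt <- mk_tensor(4, 3, 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxon_tensor(tt, path)
  tt2 <- load_taxon_tensor(path)
  expect_equal(tt2$values, tt$values)
})

test_that("TPM normalization scales samples to 1e6 and is scale-invariant", {
  arr <- array(0, dim = c(1, 2, 1), dimnames = list("g1", c("K1", "K2"), "s1"))
  arr[1, , 1] <- c(3, 3)
  tt <- taxon_tensor(arr)
  tpm <- tpm_normalize(tt)
  expect_equal(as.numeric(tpm$values[1, , 1]), c(5e5, 5e5))

  tt2 <- mk_tensor(5, 4, 6, seed = 3)
  tpm2 <- tpm_normalize(tt2)
  expect_true(all(abs(apply(tpm2$values, 3, sum) / 1e6 - 1) < 1e-9))
  # scaling all counts of the tensor by a constant leaves TPM unchanged
  tt3 <- taxon_tensor(tt2$values * 7.5)
  expect_equal(tpm_normalize(tt3)$values, tpm2$values, tolerance = 1e-12)

  arr0 <- array(0, dim = c(2, 2, 2),
                dimnames = list(paste0("g", 1:2), paste0("K", 1:2), paste0("s", 1:2)))
  arr0[, , 1] <- 1
  expect_error(tpm_normalize(taxon_tensor(arr0)), "s2")
})

test_that("group profiles match brute-force averaging and exchangeability", {
  withr::with_seed(6, {
    n <- 12
    tt <- tpm_normalize(mk_tensor(3, 2, n, seed = 6))
    dimnames(tt$values)[[3]] <- sprintf("s%02d", 1:n)
    meta <- mk_meta(rep(c("HC", "iRBD", "PD"), each = 4))
    prof <- genus_group_profiles(tt, meta)
    # brute force one cell
    hc <- which(meta$group == "HC")
    expect_equal(
      prof$cells$mean_tpm[prof$cells$genus == "g2" & prof$cells$ko == "K01" &
                            prof$cells$group == "HC"],
      mean(tt$values["g2", "K01", hc]))
    expect_equal(
      prof$genus_totals$sqrt_total,
      sqrt(prof$genus_totals$total))
    # permuting samples within a group leaves means unchanged
    perm <- c(sample(hc), setdiff(1:n, hc))
    tt_p <- taxon_tensor(tt$values[, , perm], tpm = TRUE)
    prof_p <- genus_group_profiles(tt_p, meta[perm, ] |> cohort_metadata())
    expect_equal(dplyr::arrange(prof_p$cells, genus, ko, group),
                 dplyr::arrange(prof$cells, genus, ko, group))
  })
})

test_that("Canberra distance follows the zero-term convention", {
  m <- rbind(a = c(1, 2, 0), b = c(1, 2, 0), c = c(2, 0, 4))
  d <- as.matrix(canberra_distance(m))
  expect_equal(d["a", "b"], 0)                      # identical rows
  # hand: |1-2|/3 + |2-0|/2 + |0-4|/4 = 1/3 + 1 + 1
  expect_equal(d["a", "c"], 1 / 3 + 1 + 1)
  # zero/zero terms contribute 0 (no rescaling)
  m2 <- rbind(x = c(0, 1), y = c(0, 3))
  expect_equal(as.matrix(canberra_distance(m2))["x", "y"], 0.5)
})

test_that("genus clustering recovers planted opposite fold-change blocks", {
  withr::with_seed(7, {
    n <- 16
    meta <- mk_meta(rep(c("HC", "PD"), each = n / 2))
    n_gen <- 10; n_ko <- 6
    arr <- array(0, dim = c(n_gen, n_ko, n),
                 dimnames = list(sprintf("g%02d", 1:n_gen), sprintf("K%d", 1:n_ko),
                                 meta$sample))
    for (g in 1:n_gen) {
      up_in_hc <- g <= 5
      for (s in 1:n) {
        hc <- meta$group[s] == "HC"
        mu <- if (xor(up_in_hc, !hc)) 200 else 10
        arr[g, , s] <- rpois(n_ko, mu)
      }
    }
    tpm <- tpm_normalize(taxon_tensor(arr))
    prof <- genus_group_profiles(tpm, meta)
    cl <- cluster_genera(prof, pair = c("HC", "PD"), k = 2)
    blocks <- split(cl$genus, cl$cluster)
    expect_setequal(blocks[[1]],
                    if ("g01" %in% blocks[[1]]) sprintf("g%02d", 1:5) else sprintf("g%02d", 6:10))
    # determinism: identical input, identical assignment and dendrogram order
    cl2 <- cluster_genera(prof, pair = c("HC", "PD"), k = 2)
    expect_identical(cl, cl2)
    # k = number of genera -> singletons
    cl_n <- cluster_genera(prof, pair = c("HC", "PD"), k = n_gen)
    expect_equal(dplyr::n_distinct(cl_n$cluster), n_gen)
    expect_error(cluster_genera(prof, k = n_gen + 1), "exceeds")
  })
})

test_that("collapsing the tensor reproduces the funMT restriction", {
  st <- suppressWarnings(generate_study("paper-like", seed = 3,
                       dims = list(n_taxa = 30, n_ko = 60, n_tensor_ko = 20,
                                   mm_untargeted = 40, n_unidentified = 5,
                                   n_mm_diff = 6, n_hc = 8, n_irbd = 6, n_pd = 8)))
  collapsed <- collapse_tensor(st$tensor)
  expect_equal(unname(collapsed$values[st$truth$tensor_kos, ]),
               unname(st$layers$funMT$values[st$truth$tensor_kos, ]))
})

test_that("flagellar report flags planted suppression in the right genus", {
  withr::with_seed(9, {
    n <- 36
    meta <- mk_meta(rep(c("HC", "iRBD", "PD"), each = n / 3))
    panel <- flagellar_gene_panel()
    genera <- c("gSup", "gOk", "gBackground")
    # the background genus carries most of the mass so per-sample TPM
    # totals are stable when one genus is suppressed
    arr <- array(rpois(3 * 5 * n, 50), dim = c(3, 5, n),
                 dimnames = list(genera, unname(panel), meta$sample))
    arr["gBackground", , ] <- rpois(5 * n, 2000)
    arr["gSup", , meta$group == "PD"] <-
      rpois(5 * sum(meta$group == "PD"), 3)
    tpm <- tpm_normalize(taxon_tensor(arr))
    rep <- extracellular_flagellar_report(tpm, meta, genera = c("gSup", "gOk"))
    omni <- rep[rep$comparison == "omnibus", ]
    expect_true(all(omni$q[omni$genus == "gSup"] < 0.05))
    # at most one chance finding among the unsuppressed genus rows
    expect_lte(sum(omni$q[omni$genus == "gOk"] < 0.05), 1)
    # absent gene -> flagged rows
    rep2 <- extracellular_flagellar_report(tpm, meta,
                                           genes = c(fliX = "K99999"),
                                           genera = genera)
    expect_true(all(rep2$flag == "gene_absent"))
  })
})
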
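test_that("differential_ko separates layers and flags absent KOs", {
  withr::with_seed(41, {
    n <- 30
    meta <- mk_meta(rep(c("HC", "PD"), each = n / 2))
    mg <- sum_normalize(mk_table(matrix(rlnorm(10 * n), 10),
                                 features = sprintf("K%02d", 1:10),
                                 samples = sprintf("s%02d", 1:n), layer = "funMG"))
    mt <- sum_normalize(mk_table(matrix(rlnorm(10 * n), 10),
                                 features = sprintf("K%02d", 1:10),
                                 samples = sprintf("s%02d", 1:n), layer = "funMT"))
    diff <- differential_ko(mg, mt, meta, c("K01", "K02", "K99"), c("HC", "PD"))
    expect_setequal(unique(diff$layer), c("funMG", "funMT"))
    absent <- diff[diff$feature == "K99", ]
    expect_true(all(absent$flag == "ko_absent"))
    expect_true(all(is.na(absent$p)))
    # null KOs: no q below 0.05 expected at this scale, and none tiny
    present <- diff[diff$feature != "K99", ]
    expect_true(all(present$q > 0.05))
  })
})

test_that("log2 fold change of means 4 vs 1 approaches 2 as eps -> 0", {
  n <- 20
  meta <- mk_meta(rep(c("HC", "PD"), each = n / 2))
  vals <- matrix(0.5, 2, n)
  vals[1, meta$group == "HC"] <- 4e-3
  vals[1, meta$group == "PD"] <- 1e-3
  # feature 2 carries the rest of the mass so columns sum to 1
  vals[2, ] <- 1 - colSums(vals[1, , drop = FALSE])
  t <- mk_table(vals, features = c("K1", "K2"), samples = sprintf("s%02d", 1:n),
                layer = "funMG", normalized = TRUE)
  diff <- differential_ko(t, t, meta, "K1", c("HC", "PD"))
  # eps = half the smallest positive value = 5e-4; log2((4+0.5)/(1+0.5)) scale
  expect_equal(diff$effect[1], log2((4e-3 + 5e-4) / (1e-3 + 5e-4)), tolerance = 1e-12)
  expect_lt(abs(diff$effect[1] - 2), 0.6)
})

test_that("transcript-only planted KOs dissociate between layers", {
  withr::with_seed(42, {
    n <- 60
    meta <- mk_meta(rep(c("HC", "PD"), each = n / 2))
    n_ko <- 40
    planted <- sprintf("K%02d", 1:10)
    base <- rlnorm(n_ko, 0, 1)
    mg_counts <- matrix(rpois(n_ko * n, base * 200), n_ko,
                        dimnames = list(sprintf("K%02d", 1:n_ko), meta$sample))
    mult <- matrix(1, n_ko, n, dimnames = dimnames(mg_counts))
    mult[planted, meta$group == "PD"] <- 0.25
    mt_counts <- matrix(rpois(n_ko * n, outer(base * 200, rep(1, n)) * mult),
                        n_ko, dimnames = dimnames(mg_counts))
    mg <- sum_normalize(omics_table(mg_counts, "funMG"))
    mt <- sum_normalize(omics_table(mt_counts, "funMT"))
    diff <- differential_ko(mg, mt, meta, rownames(mg_counts), c("HC", "PD"))
    mt_sig <- diff$feature[diff$layer == "funMT" & diff$q < 0.05]
    mg_sig <- diff$feature[diff$layer == "funMG" & diff$q < 0.05]
    expect_gte(mean(planted %in% mt_sig), 0.8)
    expect_lte(length(mg_sig), 2)
  })
})

test_that("per-KO taxonomic Shannon behaves at the boundaries", {
  arr <- array(0, dim = c(4, 2, 3),
               dimnames = list(paste0("g", 1:4), c("K1", "K2"), paste0("s", 1:3)))
  arr[1, "K1", 1] <- 10                      # one genus expresses K1 in s1
  arr[, "K1", 2] <- c(5, 5, 5, 5)            # four genera equally in s2
  # K1 in s3 stays all-zero
  arr[, "K2", ] <- 1
  tt <- taxon_tensor(arr)
  h <- ko_taxon_shannon(tt, "K1")
  expect_equal(h$shannon[h$sample == "s1"], 0)
  expect_equal(h$shannon[h$sample == "s2"], log(4))
  expect_true(is.na(h$shannon[h$sample == "s3"]))
  expect_error(ko_taxon_shannon(tt, "K9"), "not in tensor")
  # H = 0 iff exactly one genus has positive expression
  expect_true(all(na.omit(ko_taxon_shannon(tt, "K2")$shannon) > 0))
})

test_that("Shannon vectors feed the generic group machinery consistently", {
  withr::with_seed(43, {
    n <- 18
    tt <- mk_tensor(n_genus = 5, n_ko = 1, n_samp = n, lambda = 40)
    dimnames(tt$values)[[3]] <- sprintf("s%02d", 1:n)
    meta <- mk_meta(rep(c("HC", "iRBD", "PD"), each = 6))
    h <- ko_taxon_shannon(tt, "K01")
    t_h <- mk_table(matrix(h$shannon, 1), features = "K01_shannon",
                    samples = h$sample, layer = "funMT")
    diff <- kruskal_dunn(t_h, meta)
    ref <- kruskal.test(h$shannon, meta$group)
    expect_equal(diff$statistic[diff$comparison == "omnibus"],
                 as.numeric(ref$statistic), tolerance = 1e-12)
  })
})

test_that("Spearman correlation matches closed form and sign symmetry", {
  n <- 12
  x <- c(3, 1, 4, 1.5, 5, 9, 2, 6, 5.5, 3.5, 8, 7)
  t_mm <- mk_table(matrix(x, 1), features = "m1", samples = sprintf("s%02d", 1:n),
                   layer = "MM")
  t_up <- mk_table(matrix(x^2, 1), features = "f_up", samples = sprintf("s%02d", 1:n))
  res <- metabolite_feature_correlation(t_mm, t_up)
  expect_equal(res$rho, 1)

  t_dn <- mk_table(matrix(max(x) - x + 1, 1), features = "f_dn",
                   samples = sprintf("s%02d", 1:n))
  expect_equal(metabolite_feature_correlation(t_mm, t_dn)$rho, -1)

  # closed form on n = 5 without ties
  x5 <- c(1, 2.2, 3.1, 4.7, 5.3); y5 <- c(2, 1.1, 4.4, 3.3, 5.5)
  t_x <- mk_table(matrix(x5, 1), features = "m", samples = paste0("s", 1:5), layer = "MM")
  t_y <- mk_table(matrix(y5, 1), features = "f", samples = paste0("s", 1:5))
  got <- metabolite_feature_correlation(t_x, t_y)
  expect_equal(got$rho, spearman_closed_form(x5, y5), tolerance = 1e-12)

  # constant vector flagged, rho undefined
  t_c <- mk_table(matrix(rep(2, 5), 1), features = "c", samples = paste0("s", 1:5))
  res_c <- metabolite_feature_correlation(t_x, t_c)
  expect_true(is.na(res_c$rho))
  expect_equal(res_c$flag, "constant")
})

test_that("pathway panel tallies partition the pathway and recover planted suppression", {
  withr::with_seed(44, {
    n <- 40
    meta <- mk_meta(rep(c("HC", "PD"), each = n / 2))
    n_ko <- 12
    kos <- sprintf("K%02d", 1:n_ko)
    base <- rlnorm(n_ko, 2, 0.3)
    mult <- matrix(1, n_ko, n, dimnames = list(kos, meta$sample))
    mult[1:8, meta$group == "PD"] <- 0.15     # pathway suppressed in PD
    counts_mt <- matrix(rpois(n_ko * n, outer(base * 30, rep(1, n)) * mult),
                        n_ko, dimnames = list(kos, meta$sample))
    counts_mg <- matrix(rpois(n_ko * n, outer(base * 30, rep(1, n))),
                        n_ko, dimnames = list(kos, meta$sample))
    mg <- sum_normalize(omics_table(counts_mg, "funMG"))
    mt <- sum_normalize(omics_table(counts_mt, "funMT"))
    arr <- array(rpois(3 * n_ko * n, 20), dim = c(3, n_ko, n),
                 dimnames = list(paste0("g", 1:3), kos, meta$sample))
    tensor <- taxon_tensor(arr)
    pp <- pathway_panel(mg, mt, tensor, meta, kos[1:8], c("HC", "PD"))
    tl <- pp$tally[pp$tally$layer == "funMT", ]
    expect_equal(tl$down + tl$up + tl$unchanged, 8)
    expect_gte(tl$down, 6)                    # planted suppression recovered
    expect_equal(tl$up, 0)
    expect_error(pathway_panel(mg, mt, tensor, meta, character()), "empty pathway")
    # pathway absent from the data -> all rows flagged
    pp2 <- pathway_panel(mg, mt, tensor, meta, c("KX1", "KX2"), c("HC", "PD"))
    expect_true(all(tidy(pp2)$flag == "ko_absent"))
  })
})
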
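meta3 <- function(n_per = 3) mk_meta(rep(c("HC", "iRBD", "PD"), each = n_per))

test_that("Kruskal-Wallis matches the rank-arithmetic hand computation", {
  t <- mk_table(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 1), features = "f1",
                samples = sprintf("s%02d", 1:9))
  diff <- kruskal_dunn(t, meta3())
  h_hand <- kw_by_hand(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  omni <- diff[diff$comparison == "omnibus", ]
  expect_equal(omni$statistic, h_hand, tolerance = 1e-12)
  expect_equal(omni$p, stats::pchisq(h_hand, df = 2, lower.tail = FALSE))
})

test_that("a feature constant across all samples gets p = q = 1 with a flag", {
  m <- rbind(rep(5, 9), c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  t <- mk_table(m, samples = sprintf("s%02d", 1:9))
  diff <- kruskal_dunn(t, meta3())
  const <- diff[diff$feature == "f01", ]
  expect_true(all(const$p == 1))
  expect_true(all(const$q == 1))
  expect_true(all(const$flag == "constant"))
})

test_that("Dunn z-statistics are antisymmetric and BH keeps q >= p", {
  withr::with_seed(31, {
    t <- mk_table(matrix(rlnorm(20 * 15), 20), samples = sprintf("s%02d", 1:15))
    meta <- mk_meta(rep(c("HC", "iRBD", "PD"), each = 5))
    diff <- kruskal_dunn(t, meta)
    expect_true(all(diff$q >= diff$p - 1e-15))
    # antisymmetry: recompute with the pair roles swapped by relabeling groups
    meta_sw <- meta
    meta_sw$group <- factor(
      dplyr::recode(as.character(meta$group), HC = "PD", PD = "HC"),
      levels = c("HC", "iRBD", "PD"))
    diff_sw <- kruskal_dunn(t, meta_sw)
    z1 <- diff[diff$comparison == "HC_vs_PD", ]
    z2 <- diff_sw[diff_sw$comparison == "HC_vs_PD", ]
    expect_equal(z1$statistic, -z2$statistic, tolerance = 1e-12)
    expect_equal(z1$p, z2$p, tolerance = 1e-12)
  })
})

test_that("omnibus statistics agree with kruskal.test under heavy ties", {
  withr::with_seed(99, {
    t <- mk_table(matrix(rpois(25 * 18, 3), 25), samples = sprintf("s%02d", 1:18))
    meta <- mk_meta(rep(c("HC", "iRBD", "PD"), each = 6))
    diff <- kruskal_dunn(t, meta)
    omni <- diff[diff$comparison == "omnibus", ]
    for (f in c("f01", "f10", "f25")) {
      ref <- kruskal.test(t$values[f, ], meta$group)
      expect_equal(omni$statistic[omni$feature == f], as.numeric(ref$statistic),
                   tolerance = 1e-12)
      expect_equal(omni$p[omni$feature == f], as.numeric(ref$p.value),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH q-values are the step-up transform with max q = max p", {
  withr::with_seed(5, {
    t <- mk_table(matrix(rlnorm(50 * 12), 50), samples = sprintf("s%02d", 1:12))
    diff <- kruskal_dunn(t, mk_meta(rep(c("HC", "iRBD", "PD"), each = 4)))
    omni <- diff[diff$comparison == "omnibus", ]
    expect_equal(omni$q, p.adjust(omni$p, "BH"))
    expect_equal(max(omni$q), max(omni$p))
  })
})

test_that("Mann-Whitney matches exact enumeration and the U identity", {
  t <- mk_table(matrix(c(1, 2, 3, 4, 5, 6), 1), samples = sprintf("s%02d", 1:6))
  meta <- mk_meta(rep(c("HC", "PD"), each = 3))
  res <- pairwise_mannwhitney(t, meta, c("HC", "PD"))
  expect_equal(res$statistic, 0)   # all HC below all PD
  expect_equal(res$p, 0.1)         # 2/20 of the C(6,3) orderings are as extreme
  expect_equal(res$direction, -1)

  res_sw <- pairwise_mannwhitney(t, meta, c("PD", "HC"))
  expect_equal(res$statistic + res_sw$statistic, 9)  # U(x,y) + U(y,x) = n1 n2

  t_id <- mk_table(matrix(rep(2, 6), 1), samples = sprintf("s%02d", 1:6))
  res_id <- pairwise_mannwhitney(t_id, meta, c("HC", "PD"))
  expect_equal(res_id$p, 1)
  expect_equal(res_id$flag, "constant")
})

test_that("variance explained follows the ANOVA decomposition", {
  # levels internally constant but different -> explained = 1
  t <- mk_table(matrix(rep(c(1, 1, 1, 5, 5, 5, 9, 9, 9), 1), 1),
                samples = sprintf("s%02d", 1:9))
  ve <- variance_explained(t, meta3(), "group")
  expect_equal(ve$explained, 1)

  # identical distribution in every level -> explained ~ 0
  withr::with_seed(8, {
    x <- rnorm(60, mean = 10)
    t0 <- mk_table(matrix(x, 1), samples = sprintf("s%02d", 1:60))
    ve0 <- variance_explained(t0, mk_meta(rep(c("HC", "iRBD", "PD"), 20)), "group")
    expect_lt(ve0$explained, 0.15)
  })

  # two-level hand ANOVA identity
  y <- c(2, 4, 6, 9, 11, 13)
  t2 <- mk_table(matrix(y, 1), samples = sprintf("s%02d", 1:6))
  meta2 <- mk_meta(rep(c("HC", "PD"), each = 3))
  sst <- sum((y - mean(y))^2)
  ssw <- sum((y[1:3] - mean(y[1:3]))^2) + sum((y[4:6] - mean(y[4:6]))^2)
  ve2 <- variance_explained(t2, meta2, "group")
  expect_equal(ve2$explained, 1 - ssw / sst, tolerance = 1e-12)

  # affine invariance
  t2b <- mk_table(matrix(7 * y - 3, 1), samples = sprintf("s%02d", 1:6))
  expect_equal(variance_explained(t2b, meta2, "group")$explained,
               ve2$explained, tolerance = 1e-12)

  # zero total variance -> 0 with flag
  tz <- mk_table(matrix(rep(4, 6), 1), samples = sprintf("s%02d", 1:6))
  vez <- variance_explained(tz, meta2, "group")
  expect_equal(vez$explained, 0)
  expect_equal(vez$flag, "zero_variance")
})

test_that("variance explained drops samples with a missing factor value", {
  y <- c(2, 4, 6, 9, 11, 13)
  t <- mk_table(matrix(y, 1), samples = sprintf("s%02d", 1:6))
  meta <- mk_meta(rep(c("HC", "PD"), each = 3))
  meta$sex[5:6] <- NA
  ve <- variance_explained(t, meta, "sex")
  expect_equal(ve$n_used, 4)
})

test_that("significant_compounds filters the omnibus family and annotates contrasts", {
  empty <- significant_compounds(tibble::tibble(
    feature = character(), comparison = character(), p = numeric(),
    q = numeric(), direction = numeric()))
  expect_equal(nrow(empty), 0)

  withr::with_seed(13, {
    n_per <- 12
    meta <- mk_meta(rep(c("HC", "iRBD", "PD"), each = n_per))
    base <- matrix(rlnorm(30 * 36), 30)
    base[1:4, meta$group == "PD"] <- base[1:4, meta$group == "PD"] * 8
    t <- mk_table(base, samples = sprintf("s%02d", 1:36))
    diff <- kruskal_dunn(t, meta)
    sig <- significant_compounds(diff, 0.05)
    expect_true(all(c("f01", "f02", "f03", "f04") %in% sig$feature))
    expect_true(all(grepl("PD", sig$contrasts[sig$feature == "f01"])))
    expect_true(all(sig$q < 0.05))
  })
})
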
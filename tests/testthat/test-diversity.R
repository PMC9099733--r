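test_that("allele frequencies count het calls as one copy and skip missing", {
  gm <- tiny_gm(rbind(a = c(0L, 0L, 2L), b = c(0L, 0L, NA),
                      c = c(2L, 0L, NA), d = c(2L, 0L, NA),
                      e = c(1L, 0L, NA), f = c(1L, 0L, NA)))
  f <- allele_freq(gm)
  expect_equal(unname(f$p), c(0.5, 0, 1))
  expect_equal(unname(f$n), c(6, 6, 1))
  gm_allmiss <- tiny_gm(rbind(a = c(NA, 0L), b = c(NA, 2L)))
  expect_true(is.na(allele_freq(gm_allmiss)$p[1]))
})

test_that("PIC follows the diversity form with maximum 0.5", {
  expect_equal(pic(0), 0)
  expect_equal(pic(0.5), 0.5)
  expect_equal(pic(0.9), 0.18)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(pic(p) <= 0.5 + 1e-12))
})

test_that("uHe applies the small-sample correction and obeys its identity", {
  expect_equal(unbiased_he(0.5, 2), 2 / 3)
  expect_equal(unbiased_he(0, 7), 0)
  expect_equal(unbiased_he(0.5, 1e9), 0.5, tolerance = 1e-8)
  # algebraic identity: uHe (2n-1)/(2n) + p^2 + (1-p)^2 = 1
  set.seed(1)
  p <- runif(50)
  n <- sample(2:40, 50, replace = TRUE)
  lhs <- unbiased_he(p, n) * (2 * n - 1) / (2 * n) + p^2 + (1 - p)^2
  expect_equal(lhs, rep(1, 50))
  # ordering: PIC <= He <= uHe for finite n
  he <- 1 - p^2 - (1 - p)^2
  expect_true(all(pic(p) <= he + 1e-12 & he <= unbiased_he(p, n) + 1e-12))
})

test_that("the fixation index matches the published mean triple", {
  expect_equal(round(fixation_index(0.058, 0.197), 3), 0.706)
  expect_equal(fixation_index(0.2, 0.2), 0)
  expect_equal(fixation_index(0, 0.3), 1)
  expect_equal(fixation_index(0.1, 0), 0)    # monomorphic convention
})

test_that("observed heterozygosity counts the share of het calls", {
  tp <- toy_panel()
  ho <- observed_het(tp$genotypes)
  expect_equal(ho$ho[["L01"]], 1 / 3)
  expect_equal(ho$ho[["L03"]], 0)
  gm <- tiny_gm(matrix(1L, 3, 1))
  expect_equal(observed_het(gm)$ho[[1]], 1)
})

test_that("closed-form rarefaction equals brute-force enumeration", {
  # N = 4 copies split 2/2, g = 2: 2 * (1 - C(2,2)/C(4,2)) = 5/3
  expect_equal(dartpool:::rarefied_allele_count(4, 2, 2), 5 / 3)
  for (N in c(4, 6, 8)) {
    for (Na in 0:N) {
      for (g in 2:min(N, 6)) {
        expect_equal(dartpool:::rarefied_allele_count(N, Na, g),
                     brute_rarefied_richness(N - Na, Na, g),
                     tolerance = 1e-12,
                     label = sprintf("N=%d Na=%d g=%d", N, Na, g))
      }
    }
  }
})

test_that("allelic richness hits its analytic anchors per group", {
  gm <- tiny_gm(rbind(a = c(0L, 0L), b = c(0L, 2L),
                      c = c(0L, 1L), d = c(0L, 2L)))
  groups <- list(g1 = c("a", "b"), g2 = c("c", "d"))
  ar <- allelic_richness(gm, groups, g = 4)
  # locus 1 monomorphic -> AR 1 in both groups; g = N -> observed counts
  expect_equal(unname(ar[["g1"]]), mean(c(1, 2)))
  expect_equal(unname(ar[["g2"]]), mean(c(1, 2)))
  expect_error(allelic_richness(gm, groups, g = 1), ">= 2")
})

test_that("cultivar heterogeneity is the per-accession het fraction", {
  gm <- tiny_gm(rbind(a = c(1L, 1L, 0L, 2L), b = c(0L, 0L, 2L, 2L),
                      c = c(1L, NA, 0L, NA)))
  het <- cultivar_heterogeneity(gm)
  expect_equal(het$ho[het$accession_id == "a"], 0.5)
  expect_equal(het$ho[het$accession_id == "b"], 0)
  expect_equal(het$ho[het$accession_id == "c"], 0.5)
})

test_that("group-level heterogeneity ordering follows the generator", {
  p <- generate_panel(sim_config(
    loci_per_chromosome = c(`1H` = 300, `2H` = 300),
    group_sizes = c(12, 12), heterogeneity_by_group = c(0.2, 0.05),
    n_duplicate_pairs = 0, sweep_spec = list(), seed = 31))
  het <- cultivar_heterogeneity(p$genotypes)
  grp <- p$meta$period_group[match(het$accession_id, p$meta$accession_id)]
  means <- tapply(het$ho, grp, mean)
  expect_gt(means[[1]], means[[2]])
})

test_that("SNP-type accounting reproduces ratios from counts", {
  counts <- printed_snp_counts()
  st <- snp_type_stats(counts)
  expect_equal(st$n_ts + st$n_tv, st$n_loci)
  expect_equal(st$pct_ts + st$pct_tv, rep(100, nrow(st)))
  tot <- st[st$scope == "Total", ]
  expect_equal(tot$n_ts, 7020)
  expect_equal(round(tot$ts_tv_ratio, 2), 1.51)
  # table built from locus metadata agrees with direct counting
  tp <- toy_panel()
  tab <- snp_type_table(tp$info)
  expect_equal(sum(tab$counts[, "Total"]), 12)
  expect_equal(tab$stats$n_ts[tab$stats$scope == "Total"], 4)
  bad <- tp$info
  bad$change[2] <- "A-G"
  expect_error(snp_type_table(bad), "L02")
})

test_that("homozygous-locus fractions respect subset monotonicity", {
  tp <- toy_panel()
  full <- homozygous_locus_fraction(tp$genotypes, tp$info)
  overall <- full$fraction_homozygous[full$scope == "overall"]
  expect_equal(overall, mean(colSums(unclass(tp$genotypes) == 1L,
                                     na.rm = TRUE) == 0))
  sub <- genotype_matrix(unclass(tp$genotypes)[1:3, , drop = FALSE])
  sub_frac <- homozygous_locus_fraction(sub)$fraction_homozygous
  expect_gte(sub_frac, overall)
})

test_that("group summaries cover all scopes and degenerate cells", {
  tp <- toy_panel()
  gs <- group_summaries(tp$genotypes, tp$info, tp$meta)
  expect_setequal(unique(gs$scope),
                  c("panel", "chromosome", "group", "group_x_chromosome"))
  # single-chromosome restriction equals whole-panel summary
  on1h <- tp$info$chromosome == "1H"
  sub <- genotype_matrix(unclass(tp$genotypes)[, on1h, drop = FALSE])
  gs1 <- group_summaries(sub, tp$info[on1h, ], NULL)
  expect_equal(gs1$pic_mean[gs1$scope == "panel"],
               gs$pic_mean[gs$scope == "chromosome" & gs$chromosome == "1H"])
  # 4H has one locus; the toy panel has no loci on e.g. 4H for a group after
  # subsetting to a chromosome with no loci -> NA cell
  none <- gs[gs$scope == "chromosome" & gs$chromosome == "Un", ]
  expect_equal(none$n_loci, 1L)
})

test_that("per-group uHe tracks the simulator's expected heterozygosity", {
  p <- generate_panel(sim_config(
    loci_per_chromosome = c(`1H` = 800, `2H` = 800),
    group_sizes = c(15, 15), heterogeneity_by_group = c(0.05, 0.05),
    pool_divergence = 0.01, n_duplicate_pairs = 0, sweep_spec = list(),
    rare_locus_frac = 0, seed = 17))
  gs <- group_summaries(p$genotypes, p$info, p$meta)
  # with negligible pool divergence every accession's mixture frequency is
  # ~p0, so expected uHe is the mean of 2 p0 (1 - p0)
  expected <- mean(2 * p$truth$p0 * (1 - p$truth$p0))
  got <- gs$uhe_mean[gs$scope == "group"]
  expect_true(all(abs(got - expected) < 0.02))
})

test_that("locus spacing summary reproduces the printed geometry", {
  sp <- locus_spacing_summary(printed_locus_counts())
  expect_equal(round(sp$per_chromosome$mean_distance_mbp[1], 2), 0.49)
  expect_equal(round(sp$density_kbp_per_locus / 10) * 10, 470)
})
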
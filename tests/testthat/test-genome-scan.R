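test_that("window skeletons span the chromosome with even centers", {
  tr <- make_windows(558.54e6, n_positions = 250, width_bp = 5e5)
  expect_equal(nrow(tr), 250)
  expect_equal(tr$center_bp[1], 2.5e5)
  expect_equal(tr$center_bp[250], 558.54e6 - 2.5e5)
  spacing <- diff(tr$center_bp)
  expect_equal(spacing, rep((558.54e6 - 5e5) / 249, 249), tolerance = 1e-9)
  two <- make_windows(1e6, n_positions = 2, width_bp = 4e5)
  expect_equal(two$center_bp, c(2e5, 8e5))
  expect_error(make_windows(4e5, width_bp = 5e5), "exceed")
})

test_that("window reduction honours half-open edges and empty windows", {
  tr <- make_windows(2e6, n_positions = 2, width_bp = 1e6)
  # windows: [0, 1e6) and [1e6, 2e6)
  red <- window_reduce(tr, positions = c(0, 1e6 - 1, 1e6),
                       values = c(0.1, 0.2, 0.3))
  expect_equal(red$value[1], mean(c(0.1, 0.2)))   # right edge excluded
  expect_equal(red$value[2], 0.3)                 # left edge included
  cnt <- window_reduce(tr, positions = c(0.5e6), reducer = "count")
  expect_equal(cnt$value, c(1, 0))
  expect_true(is.na(window_reduce(tr, numeric(0), numeric(0))$value[1]))
  expect_error(window_reduce(tr, c(1, 2), c(0.5)), "length")
})

test_that("window counts agree with brute-force interval queries", {
  set.seed(8)
  pos <- sort(runif(200, 0, 5e7))
  tr <- make_windows(5e7, n_positions = 40, width_bp = 2e6)
  red <- window_reduce(tr, pos, reducer = "count")
  brute <- vapply(seq_len(nrow(tr)), function(w) {
    sum(pos >= tr$center_bp[w] - 1e6 & pos < tr$center_bp[w] + 1e6)
  }, numeric(1))
  expect_equal(red$value, brute)
})

test_that("per-locus FST matches its closed form and brute-force counting", {
  # p_a = 0.2, p_b = 0.8 -> HT = 0.5, HS = 0.32, FST = 0.36
  ga <- c(0L, 0L, 0L, 0L, 2L)                # p = 0.2
  gb <- c(2L, 2L, 2L, 2L, 0L)                # p = 0.8
  gm <- tiny_gm(matrix(c(ga, gb), ncol = 1),
                ids = NULL)
  rownames(gm) <- c(paste0("a", 1:5), paste0("b", 1:5))
  fst <- fst_per_locus(gm, paste0("a", 1:5), paste0("b", 1:5))
  expect_equal(unname(fst), 0.36)
  # fixed alternative alleles -> 1; equal frequencies -> 0
  gm2 <- tiny_gm(rbind(x1 = c(0L, 1L), x2 = c(0L, 1L),
                       y1 = c(2L, 1L), y2 = c(2L, 1L)))
  fst2 <- fst_per_locus(gm2, c("x1", "x2"), c("y1", "y2"))
  expect_equal(unname(fst2), c(1, 0))
  # toy panel against the independent counting oracle
  tp <- toy_panel()
  g <- unclass(tp$genotypes)
  got <- fst_per_locus(tp$genotypes, c("A1", "A2"), c("A3", "A4"))
  for (l in seq_len(ncol(g))) {
    expect_equal(unname(got[l]), brute_fst(g[1:2, l], g[3:4, l]),
                 label = colnames(g)[l])
  }
})

test_that("the FST power transform is monotone with fixed endpoints", {
  expect_equal(fst_transform(c(0, 1)), c(0, 1))
  expect_equal(fst_transform(0.5), 0.5^10)
  v <- seq(0, 1, by = 0.1)
  expect_true(all(diff(fst_transform(v)) >= 0))
  expect_error(fst_transform(c(-0.1)), "TRUE|>= 0")
})

test_that("unique alleles use an inclusive frequency threshold", {
  # earlier group: alt at 0.3 (lost), later absent; second locus alt at 0.2
  ge <- rbind(e1 = c(1L, 0L), e2 = c(1L, 1L), e3 = c(1L, 0L),
              e4 = c(0L, 1L), e5 = c(0L, 0L))
  gl <- rbind(l1 = c(0L, 0L), l2 = c(0L, 0L), l3 = c(0L, 0L),
              l4 = c(0L, 0L), l5 = c(0L, 0L))
  gm <- tiny_gm(rbind(ge, gl))
  info <- locus_info(data.frame(
    locus_id = colnames(gm), chromosome = c("2H", "2H"),
    position_bp = c(1e6, 2e6), change = c("A>G", "C>T"),
    rep_avg = 0.99, call_rate = 1, stringsAsFactors = FALSE))
  ua25 <- unique_alleles(gm, info, rownames(ge), rownames(gl), 0.25)
  expect_equal(sum(ua25$by_chromosome$n_lost), 1)       # 0.3 >= 0.25; 0.2 not
  ua05 <- unique_alleles(gm, info, rownames(ge), rownames(gl), 0.05)
  expect_equal(sum(ua05$by_chromosome$n_lost), 2)
  expect_equal(sum(ua25$by_chromosome$n_gained), 0)
  expect_error(unique_alleles(gm, info, rownames(ge), rownames(gl), 0),
               "threshold")
  expect_error(unique_alleles(gm, info, rownames(ge), rownames(ge)),
               "disjoint")
})

test_that("a planted sweep surfaces as lost ref alleles and a top window", {
  # locus-dense 5H with an edge-adjacent sweep so the narrow 500 kb windows
  # inside the sweep span actually contain sweep loci
  cfg <- sim_config(
    loci_per_chromosome = c(`3H` = 300, `5H` = 1500),
    group_sizes = c(20, 20), heterogeneity_by_group = c(0.05, 0.05),
    pool_divergence = 0.05, n_duplicate_pairs = 0,
    sweep_spec = list(list(chromosome = "5H", center_bp = 100e6,
                           width_bp = 100e6, groups = 2L)),
    rare_locus_frac = 0, missing_rate = 0, seed = 41)
  p <- generate_panel(cfg)
  groups <- period_split(p$meta)
  ua <- unique_alleles(p$genotypes, p$info, groups[[1]], groups[[2]], 0.25)
  lost_on_5h <- ua$by_chromosome$n_lost[ua$by_chromosome$chromosome == "5H"]
  expect_gt(lost_on_5h, 0)
  expect_true(any(ua$lost_loci %in% p$truth$sweep_loci))

  scan <- selection_scan_report(p$genotypes, p$info, groups[[1]], groups[[2]],
                                n_positions = 250)
  top <- scan$fst_pow[which.max(scan$fst_pow$value), ]
  expect_equal(top$chromosome, "5H")
  expect_true(abs(top$center_bp - 100e6) <= 50e6 + top$half_width_bp)
})

test_that("a null contrast leaves windowed FST^10 flat", {
  p <- generate_panel(sim_config(
    loci_per_chromosome = c(`1H` = 500, `2H` = 500),
    group_sizes = c(20, 20), heterogeneity_by_group = c(0.05, 0.05),
    pool_divergence = 0.003, n_duplicate_pairs = 0, sweep_spec = list(),
    seed = 43))
  groups <- period_split(p$meta)
  scan <- selection_scan_report(p$genotypes, p$info, groups[[1]], groups[[2]],
                                n_positions = 100)
  expect_lt(max(scan$fst_pow$value, na.rm = TRUE), 1e-3)
})

test_that("PIC tracks coincide for groups with identical genotypes", {
  set.seed(2)
  calls <- matrix(sample(c(0L, 1L, 2L), 40, replace = TRUE), 4, 10)
  gm <- tiny_gm(rbind(calls, calls))         # second group duplicates first
  info <- locus_info(data.frame(
    locus_id = colnames(gm), chromosome = "1H",
    position_bp = seq(1e6, 5e8, length.out = 10), change = "A>G",
    rep_avg = 0.99, call_rate = 1, stringsAsFactors = FALSE))
  scan <- selection_scan_report(gm, info, rownames(gm)[1:4],
                                rownames(gm)[5:8], n_positions = 20,
                                width_bp = 60e6)
  expect_equal(scan$pic_a$value, scan$pic_b$value)
  expect_equal(max(scan$fst_pow$value, na.rm = TRUE), 0)
})
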
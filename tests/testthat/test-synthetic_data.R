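test_that("scenario invariants are enforced", {
  expect_error(sim_scenario(Tr = 25, Td = 25), "Tr < Td")
  expect_error(sim_scenario(Np = 300, Tr = 8), "2\\^Tr")
  expect_error(sim_scenario(dropout = 1), "dropout")
  expect_error(scenario_cohort(sim_scenario(mode = "static")), "ages_days")
})

test_that("prefix genealogies encode ancestry through longest common prefixes", {
  set.seed(2)
  scn <- sim_scenario()
  gen <- simulate_genealogy(scn)
  expect_equal(nrow(gen), 2L * scn$s)
  expect_true(all(nchar(gen$path) == scn$Td))
  sep <- true_separation(gen)
  expect_equal(sep, t(sep))
  # identical paths mean zero separation
  twin <- gen[c(1, 1), ]
  expect_true(all(true_separation(twin) == 0))
  # focal and complement populations split at or before the restriction division
  cross <- sep[gen$population == "oocyte", gen$population == "other"]
  expect_true(all(cross >= 2 * (scn$Td - scn$Tr)))
})

test_that("prefix sampling matches an explicit full-tree simulation at small depth", {
  set.seed(4)
  Td <- 12L
  scn <- sim_scenario(Td = Td, Tr = 4L, s = 40L)
  gen <- simulate_genealogy(scn, restrict = FALSE)
  pairs <- t(combn(nrow(gen), 2))[sample(choose(nrow(gen), 2), 500), ]
  sep_pkg <- apply(pairs, 1, function(ij)
    true_separation(gen[ij, ])[1, 2])
  # oracle: materialize all 2^Td leaves as integers; the divergence of two
  # uniformly drawn leaves is read off their binary representations
  leaves <- sample.int(2^Td, 1000, replace = TRUE) - 1L
  int_lcp <- function(x, y) {
    d <- 0L
    for (b in (Td - 1L):0) {
      if (bitwAnd(x, 2^b) == bitwAnd(y, 2^b)) d <- d + 1L else break
    }
    d
  }
  sep_oracle <- vapply(seq(1, 999, by = 2), function(i)
    2 * (Td - int_lcp(leaves[i], leaves[i + 1])), numeric(1))
  ks <- suppressWarnings(ks.test(sep_pkg, sep_oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("mutation and measurement honour the generative corners", {
  set.seed(6)
  quiet <- sim_scenario(mu = 0, dropout = 0, s = 5L, n_loci = 10L)
  cells <- mutate_and_measure(simulate_genealogy(quiet,
                                                 include_other = FALSE),
                              quiet, panel = make_panel(10L))
  expect_true(all(vapply(cells, function(cl) all(cl$deviations == 0),
                         logical(1))))
  expect_true(all(vapply(cells, function(cl) length(cl$deviations) == 20L,
                         logical(1))))

  # expected number of mutant alleles per cell from the pmf itself
  scn <- sim_scenario(dropout = 0)
  sim_cells <- mutate_and_measure(simulate_genealogy(scn,
                                                     include_other = FALSE),
                                  scn)
  p_mut <- 1 - step_diff_pmf(0, scn$Td, scn$mu)
  n_mut <- vapply(sim_cells, function(cl) sum(cl$deviations != 0), numeric(1))
  se <- sqrt(162 * p_mut * (1 - p_mut) / length(n_mut))
  expect_lt(abs(mean(n_mut) - 162 * p_mut), 3 * se + 1e-9)

  # dropout thins observed alleles to ~(1 - rate)
  drop <- sim_scenario()
  dcells <- mutate_and_measure(simulate_genealogy(drop,
                                                  include_other = FALSE),
                               drop)
  frac <- mean(vapply(dcells, function(cl) length(cl$deviations), numeric(1))) / 162
  expect_lt(abs(frac - 0.675), 0.06)
})

test_that("cohort scenarios produce the depth structure they claim", {
  # static: no age effect
  set.seed(31)
  scn_s <- sim_scenario(mode = "static", ages_days = c(27, 268), s = 15L)
  diffs <- replicate(6, {
    summ <- cohort_depth_summaries(scenario_cohort(scn_s))
    diff(summ$median_depth)
  })
  expect_lt(abs(mean(diffs)), 2)

  # renewal at 2 divisions / 100 days: ~4.8 extra divisions over 241 days
  scn_r <- sim_scenario(mode = "renewal", ages_days = c(27, 268), s = 15L)
  rdiffs <- replicate(6, {
    summ <- cohort_depth_summaries(scenario_cohort(scn_r))
    diff(summ$median_depth)
  })
  expect_gt(mean(rdiffs), 2.8)
  expect_lt(mean(rdiffs), 6.8)

  # production line: the 12-day mouse samples the full width of the fixed
  # birth distribution while old mice sample narrow quantile bands
  set.seed(35)
  scn_p <- sim_scenario(mode = "production_line",
                        ages_days = c(12, 100, 200, 300), s = 25L)
  d12 <- replicate(20, mslineage:::scenario_depths(scn_p, 12, 1, 4))
  d300 <- replicate(20, mslineage:::scenario_depths(scn_p, 300, 4, 4))
  expect_gte(diff(range(d12)), scn_p$pl_span - 1)     # full birth distribution
  expect_true(all(d300 >= scn_p$Td + 0.75 * scn_p$pl_span - 1))  # top band
  expect_gt(diff(range(d12)), diff(range(d300)))
  # through the pipeline, the top band sits above the second band
  cells <- scenario_cohort(scn_p)
  summ <- cohort_depth_summaries(cells)
  expect_gt(summ$median_depth[summ$mouse_id == "M300"],
            summ$median_depth[summ$mouse_id == "M100"])
})

test_that("identical scenarios and seeds reproduce byte-identical tables", {
  scn <- sim_scenario(mode = "renewal", ages_days = c(27, 159), s = 6L,
                      n_loci = 20L, pcr_repeat_pairs = 1L, seed = 99L)
  p1 <- tempfile(); p2 <- tempfile()
  write_signature_table(scenario_cohort(scn, panel = make_panel(20L)), p1)
  write_signature_table(scenario_cohort(scn, panel = make_panel(20L)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("scenario tables close the loop through I/O, QC and reconstruction", {
  set.seed(41)
  scn <- sim_scenario(s = 12L, pcr_repeat_pairs = 1L,
                      gv_multiallele_rate = 0.01)
  cells <- mutate_and_measure(simulate_genealogy(scn), scn)
  path <- tempfile(fileext = ".tsv")
  write_signature_table(cells, path)
  back <- qc_filter(read_signature_table(path, make_panel(scn$n_loci)))
  expect_gt(length(back), 20)
  rec <- reconstruct_tree(back)
  expect_true(all(rec$depths >= 0))
  expect_equal(ape::Ntip(rec$tree), length(back))
})

test_that("PCR repeats sit next to their originals on reconstructed trees", {
  set.seed(47)
  scn <- sim_scenario(s = 20L, pcr_repeat_pairs = 2L)
  sister <- replicate(10, {
    gen <- simulate_genealogy(scn, include_other = FALSE)
    cells <- mutate_and_measure(gen, scn)
    rec <- reconstruct_tree(cells)
    reps <- Filter(function(cl) !is.na(cl$pcr_repeat_of), cells)
    vapply(reps, function(cl) {
      pair <- c(cl$cell_id, cl$pcr_repeat_of)
      mrca <- ape::getMRCA(rec$tree, pair)
      length(ape::extract.clade(rec$tree, mrca)$tip.label) == 2L
    }, logical(1))
  })
  expect_gte(mean(sister), 0.9)
})

test_that("estimator benchmark measures bias and efficiency of both estimators", {
  set.seed(53)
  bench <- estimator_benchmark(Td_values = 25L, n_iter = 10L)
  expect_setequal(bench$estimator, c("tree_ml", "squared_distance"))
  expect_true(all(abs(bench$bias) < 4))       # both near the true depth
  expect_true(all(bench$sem > 0))
  b_tree <- abs(bench$bias[bench$estimator == "tree_ml"])
  b_sq <- abs(bench$bias[bench$estimator == "squared_distance"])
  expect_lte(b_tree, b_sq)                    # tree-ML less biased on clean data
  # corruption shifts both estimators upward
  set.seed(54)
  noisy <- estimator_benchmark(Td_values = 25L, n_iter = 6L,
                               signal_error_rate = 0.1)
  expect_true(all(noisy$bias > 0.5))
})

test_that("clustering power is perfect at one progenitor and weak at Np = s", {
  set.seed(59)
  pw <- progenitor_power_study(Np_grid = c(1L, 30L), s = 15L, n_trees = 8L)
  expect_equal(pw$detection_fraction[pw$Np == 1], 1)
  expect_lt(pw$detection_fraction[pw$Np == 30], 0.75)
})
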
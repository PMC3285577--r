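test_that("step pmf matches closed forms at the corners", {
  expect_equal(step_diff_pmf(0, 0, 1 / 30), 1)
  expect_equal(step_diff_pmf(c(-1, 1, 5), 0, 1 / 30), c(0, 0, 0))
  expect_equal(step_diff_pmf(1, 1, 1 / 30), 1 / 60)       # mu * 1/2
  expect_equal(step_diff_pmf(0, 1, 1 / 30), 29 / 30)
  expect_error(step_diff_pmf(0, -1, 1 / 30), "non-negative")
})

test_that("step pmf equals brute-force enumeration over mutation paths", {
  for (mu in c(1 / 10, 1 / 30)) {
    for (t in c(2L, 7L, 10L)) {
      got <- step_diff_pmf(0:t, t, mu)
      want <- vapply(0:t, bf_step_pmf, numeric(1), t = t, mu = mu)
      expect_equal(got, want, tolerance = 1e-13)
    }
  }
  expect_equal(step_diff_pmf(2, 10, 1 / 30), bf_step_pmf(2, 10, 1 / 30),
               tolerance = 1e-13)
})

test_that("step pmf is symmetric, normalized, and spreads with time", {
  for (mu in c(1 / 10, 1 / 30, 1 / 200)) {
    v_prev <- -1
    for (t in c(1L, 5L, 20L, 60L)) {
      p <- step_diff_pmf(-t:t, t, mu)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, rev(p))
      v <- sum((-t:t)^2 * p)   # variance (mean is 0)
      expect_gt(v, v_prev)
      v_prev <- v
    }
  }
})

test_that("ML pairwise distance maximizes the likelihood over integer separations", {
  keys <- sort(c(allele_key(make_panel(81L)$locus_id, "A"),
                 allele_key(make_panel(81L)$locus_id, "B")))
  model <- stepwise_model()
  a <- tiny_cell("a", setNames(rep(0L, 50), keys[1:50]))
  expect_equal(ml_pairwise_distance(a, a, model)$t_hat, 0L)

  dev_b <- setNames(rep(0L, 50), keys[1:50]); dev_b[1] <- 2L
  b <- tiny_cell("b", dev_b)
  got <- ml_pairwise_distance(a, b, model)
  # exhaustive scan with the independent brute-force pmf
  ll <- vapply(0:500, function(t)
    49 * log(bf_step_pmf(0, t, model$mu)) +
      log(bf_step_pmf(2, t, model$mu)), numeric(1))
  ll[!is.finite(ll)] <- -Inf
  expect_equal(got$t_hat, which.max(ll) - 1L)
  expect_equal(got$overlap, 50L)
})

test_that("pairs below the overlap threshold are undefined, not zero", {
  keys <- allele_key(sprintf("L%03d", 1:12), "A")
  a <- tiny_cell("a", setNames(rep(0L, 5), keys[1:5]))
  b <- tiny_cell("b", setNames(rep(0L, 5), keys[1:5]))
  out <- ml_pairwise_distance(a, b, stepwise_model(min_overlap = 10))
  expect_true(is.na(out$t_hat))
  expect_equal(out$overlap, 5L)
  c3 <- tiny_cell("c", setNames(rep(0L, 5), keys[6:10]))
  root <- structure(list(deviations = setNames(rep(0L, 12), keys)),
                    class = "root_signature")
  expect_error(build_distance_matrix(list(a, b, c3), root, stepwise_model()),
               "undefined")
})

test_that("simulated separations are recovered within tolerance", {
  set.seed(101)
  scn <- sim_scenario(dropout = 0)   # full panel, no missingness
  model <- stepwise_model()
  hits <- replicate(60, {
    # two cells separated by exactly 30 divisions: depth-15 common ancestor
    gen <- data.frame(cell_id = c("a", "b"),
                      path = c(paste0(strrep("0", 10), strrep("0", 15)),
                               paste0(strrep("0", 10), strrep("1", 15))),
                      population = "oocyte", ovary_side = NA,
                      true_depth = 25L)
    cells <- mutate_and_measure(gen, scn)
    t_hat <- ml_pairwise_distance(cells[[1]], cells[[2]], model)$t_hat
    abs(t_hat - 30) <= 10
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the distance matrix is symmetric, zero-diagonal, and bounded by the panel", {
  set.seed(3)
  scn <- sim_scenario(s = 10L)
  gen <- simulate_genealogy(scn, include_other = FALSE)
  cells <- mutate_and_measure(gen, scn)
  dm <- build_distance_matrix(cells, compute_root_signature(cells))
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(is.finite(dm$d)))
  off <- dm$overlap[upper.tri(dm$overlap)]
  expect_true(all(off < 162L) && all(off > 10L))
  expect_equal(dm$labels[length(dm$labels)], "root_median")

  same <- lapply(c("x", "y", "z"), function(id)
    tiny_cell(id, setNames(rep(1L, 30),
                           allele_key(make_panel(15L)$locus_id,
                                      rep(c("A", "B"), each = 15)))))
  dm0 <- build_distance_matrix(same, compute_root_signature(same))
  expect_true(all(dm0$d == 0))
})

test_that("mutation-rate estimation recovers the truth and flags degenerate input", {
  set.seed(11)
  scn <- sim_scenario()
  gen <- simulate_genealogy(scn, include_other = FALSE)
  cells <- mutate_and_measure(gen, scn)
  root <- compute_root_signature(cells)
  mu_hat <- estimate_mutation_rate(cells, rep(25L, length(cells)), root)
  expect_gt(mu_hat, 1 / 40)
  expect_lt(mu_hat, 1 / 22)

  keys <- allele_key(sprintf("L%03d", 1:20), "A")
  quiet <- lapply(c("a", "b"), function(id)
    tiny_cell(id, setNames(rep(0L, 20), keys)))
  root0 <- compute_root_signature(quiet)
  expect_warning(mu0 <- estimate_mutation_rate(quiet, c(25L, 25L), root0),
                 "lower grid bound")
  expect_equal(mu0, 1e-3)

  # one allele, one step, one division: likelihood mu/2 rises to the top bound
  one <- tiny_cell("a", list(`L001|A` = 1L))
  two <- tiny_cell("b", list(`L001|A` = 1L))
  r1 <- structure(list(deviations = c(`L001|A` = 0L)),
                  class = "root_signature")
  expect_equal(estimate_mutation_rate(list(one, two), c(1L, 1L), r1),
               0.5, tolerance = 1e-4)
})

test_that("squared-distance depth statistic is the mean squared deviation", {
  keys <- allele_key(sprintf("L%03d", 1:4), "A")
  root <- structure(list(deviations = setNames(rep(0L, 4), keys)),
                    class = "root_signature")
  same <- tiny_cell("a", setNames(rep(0L, 4), keys))
  expect_equal(squared_distance_depth(same, root), 0)
  mixed <- tiny_cell("b", setNames(c(1L, -1L, 0L, 0L), keys))
  expect_equal(squared_distance_depth(mixed, root), 0.5)
  expect_equal(squared_distance_depth(mixed, root, scale = 30), 15)
  lonely <- tiny_cell("c", list(`LX|A` = 1L))
  expect_error(squared_distance_depth(lonely, root), "shared")
})
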
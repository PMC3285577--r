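# Generative simulator emulating the study's data-generating process:
# binary division genealogies with progenitor restriction, symmetric
# stepwise microsatellite mutations on a diploid panel, allelic dropout,
# PCR repeats, GV-stage multiallele events, and the post-natal scenarios
# (static, renewal, production line, coherent/incoherent migration).

#' Simulation scenario
#'
#' Bundles the full generative configuration. Defaults are the study
#' conditions: trees of depth 25 divisions, lineage restriction of the focal
#' population to `Np` progenitors at division 8, 30 cells sampled per
#' population, 81 diploid loci (162 alleles), per-allele per-division
#' mutation rate 1/30, 32.5% allelic dropout.
#'
#' @param Td tree depth in divisions.
#' @param Np progenitor count of the focal population (default 5, within the
#'   3-10 range inferred for oocyte progenitors; cumulus populations have 5).
#' @param Tr restriction division at which progenitors are set aside.
#' @param s cells sampled per population.
#' @param n_loci loci in the panel (2 alleles each).
#' @param mu per-allele per-division mutation rate (0 allowed for controls).
#' @param dropout per-allele probability of amplification failure.
#' @param pcr_repeat_pairs number of cells re-measured as PCR repeats.
#' @param gv_multiallele_rate per-locus per-cell probability of a GV-stage
#'   (four-chromatid) spontaneous mutation, observed as a >2-allele locus.
#' @param p_plus probability of a +1 step (0.5 = symmetric; other values
#'   model deviations from the mutation model).
#' @param mode one of `"static"`, `"renewal"`, `"production_line"`,
#'   `"coherent_migration"`, `"incoherent_migration"`.
#' @param ages_days mouse ages for cohort scenarios.
#' @param renewal_rate extra divisions per 100 days in renewal mode.
#' @param pl_span width (divisions) of the fixed birth-time depth
#'   distribution in production-line mode.
#' @param pl_all_follicles_age age (days) at or below which all follicles are
#'   pre-antral, so sampling covers the full depth distribution.
#' @param seed integer seed used by [scenario_cohort()].
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(Td = 25L, Np = 5L, Tr = 8L, s = 30L, n_loci = 81L,
                         mu = 1 / 30, dropout = 0.325,
                         pcr_repeat_pairs = 0L, gv_multiallele_rate = 0,
                         p_plus = 0.5,
                         mode = c("static", "renewal", "production_line",
                                  "coherent_migration",
                                  "incoherent_migration"),
                         ages_days = NULL, renewal_rate = 2,
                         pl_span = 10L, pl_all_follicles_age = 14L,
                         seed = NULL) {
  mode <- match.arg(mode)
  Td <- as.integer(Td); Np <- as.integer(Np); Tr <- as.integer(Tr)
  if (!(Tr > 0 && Tr < Td)) stop("need 0 < Tr < Td")
  if (!(Np >= 1 && Np <= 2^Tr)) stop("need 1 <= Np <= 2^Tr")
  if (!(dropout >= 0 && dropout < 1)) stop("dropout must be in [0, 1)")
  if (!(mu >= 0 && mu < 1)) stop("mu must be in [0, 1)")
  structure(list(Td = Td, Np = Np, Tr = Tr, s = as.integer(s),
                 n_loci = as.integer(n_loci), mu = mu, dropout = dropout,
                 pcr_repeat_pairs = as.integer(pcr_repeat_pairs),
                 gv_multiallele_rate = gv_multiallele_rate, p_plus = p_plus,
                 mode = mode, ages_days = ages_days,
                 renewal_rate = renewal_rate, pl_span = as.integer(pl_span),
                 pl_all_follicles_age = as.integer(pl_all_follicles_age),
                 seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> mode=%s Td=%d Np=%d Tr=%d s=%d loci=%d mu=%.4g dropout=%.3f\n",
              x$mode, x$Td, x$Np, x$Tr, x$s, x$n_loci, x$mu, x$dropout))
  invisible(x)
}

int_to_bits <- function(x, width) {
  vapply(x, function(v)
    paste(rev(as.integer(intToBits(v))[seq_len(width)]), collapse = ""),
    character(1))
}

random_bits <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("0", "1"), n, replace = TRUE), collapse = "")
}

#' Simulate a division genealogy
#'
#' Cells of a complete binary division tree are identified with bit strings:
#' the path of left/right choices from the zygote. A cell sampled at depth
#' `d` is a uniformly random `d`-bit string, constrained (for the focal
#' population) to extend one of the `Np` progenitor prefixes fixed at the
#' restriction division `Tr`. Ancestry of any subset of cells is given by
#' longest common prefixes, so the complete tree is never materialized.
#' The complement population (`"other"`) samples cells outside the
#' progenitor prefixes.
#'
#' In `coherent_migration` mode the progenitors are split into two disjoint
#' halves feeding the left and right ovary; in `incoherent_migration` mode
#' both sides sample all progenitors (and `s` is the number of cells per
#' side in both migration modes).
#'
#' @param scn a [sim_scenario()].
#' @param depths optional per-cell depths for the focal population
#'   (defaults to `Td` for every cell); the complement is always at `Td`.
#' @param restrict if `FALSE`, the focal cells are unconstrained uniform
#'   samples of the whole tree and no complement is drawn (the estimator
#'   benchmark design).
#' @param include_other draw the complement population as well.
#' @return data.frame of class `true_genealogy`: `cell_id`, `path`,
#'   `population`, `ovary_side`, `true_depth`.
#' @export
simulate_genealogy <- function(scn, depths = NULL, restrict = TRUE,
                               include_other = TRUE) {
  if (scn$Np > 2^scn$Tr) stop("Np exceeds the 2^Tr nodes at the restriction division")
  if (is.null(depths)) depths <- rep(scn$Td, scn$s)
  migration <- scn$mode %in% c("coherent_migration", "incoherent_migration")
  n_focal <- if (migration) 2L * scn$s else length(depths)
  if (migration) depths <- rep_len(depths, n_focal)
  if (any(depths < scn$Tr)) stop("cell depths must be >= Tr")

  if (!restrict) {
    paths <- vapply(depths, random_bits, character(1))
    gen <- data.frame(cell_id = sprintf("c%03d", seq_along(paths)),
                      path = paths, population = "oocyte",
                      ovary_side = NA_character_, true_depth = depths,
                      stringsAsFactors = FALSE)
    class(gen) <- c("true_genealogy", "data.frame")
    return(gen)
  }

  prog_ids <- sample.int(2^scn$Tr, scn$Np) - 1L
  prog_prefix <- int_to_bits(prog_ids, scn$Tr)
  if (scn$mode == "coherent_migration") {
    if (scn$Np < 2L) stop("coherent migration needs Np >= 2")
    half <- split(prog_prefix,
                  rep(c("left", "right"), length.out = scn$Np))
    side <- rep(c("left", "right"), each = scn$s)
    pick <- vapply(side, function(sd)
      half[[sd]][sample.int(length(half[[sd]]), 1L)], character(1))
  } else {
    pick <- prog_prefix[sample.int(scn$Np, n_focal, replace = TRUE)]
    side <- if (scn$mode == "incoherent_migration") {
      rep(c("left", "right"), each = scn$s)
    } else rep(NA_character_, n_focal)
  }
  focal_paths <- vapply(seq_len(n_focal), function(i)
    paste0(pick[i], random_bits(depths[i] - scn$Tr)), character(1))
  focal <- data.frame(cell_id = sprintf("o%03d", seq_len(n_focal)),
                      path = focal_paths, population = "oocyte",
                      ovary_side = unname(side), true_depth = depths,
                      stringsAsFactors = FALSE)
  gen <- focal
  if (include_other) {
    rest <- setdiff(seq_len(2^scn$Tr) - 1L, prog_ids)
    if (!length(rest)) stop("no complement prefixes left (Np = 2^Tr)")
    opick <- int_to_bits(rest[sample.int(length(rest), scn$s, replace = TRUE)],
                         scn$Tr)
    other_paths <- vapply(opick, function(p)
      paste0(p, random_bits(scn$Td - scn$Tr)), character(1))
    other <- data.frame(cell_id = sprintf("x%03d", seq_len(scn$s)),
                        path = unname(other_paths), population = "other",
                        ovary_side = NA_character_,
                        true_depth = rep(scn$Td, scn$s),
                        stringsAsFactors = FALSE)
    gen <- rbind(focal, other)
  }
  class(gen) <- c("true_genealogy", "data.frame")
  gen
}

#' True pairwise division separation
#'
#' Divisions separating two sampled cells on the true genealogy: the sum of
#' both path lengths beyond their longest common prefix.
#'
#' @param gen a `true_genealogy`.
#' @return symmetric matrix of true separations (divisions).
#' @export
true_separation <- function(gen) {
  n <- nrow(gen)
  out <- matrix(0, n, n, dimnames = list(gen$cell_id, gen$cell_id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      l <- lcp2(gen$path[i], gen$path[j])
      out[i, j] <- out[j, i] <- (nchar(gen$path[i]) - l) +
        (nchar(gen$path[j]) - l)
    }
  }
  out
}

lcp2 <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq)) neq[1L] - 1L else n
}

# longest common prefix depth of a set of paths, starting at `from`,
# capped at the shortest path
lcp_from <- function(paths, from) {
  maxd <- min(nchar(paths))
  d <- from
  while (d < maxd) {
    b <- substr(paths, d + 1L, d + 1L)
    if (all(b == b[1L])) d <- d + 1L else break
  }
  d
}

# simulate per-allele net deviations along the induced genealogy: mutations
# on shared lineage segments are shared by all descendant cells
sim_genotypes <- function(paths, n_alleles, mu, p_plus) {
  G <- matrix(0L, nrow = length(paths), ncol = n_alleles)
  recurse <- function(idx, from, geno) {
    D <- lcp_from(paths[idx], from)
    L <- D - from
    if (L > 0L && mu > 0) {
      m <- rbinom(n_alleles, L, mu)
      up <- rbinom(n_alleles, m, p_plus)
      geno <- geno + (2L * up - m)
    }
    lens <- nchar(paths[idx])
    for (leaf in idx[lens == D]) G[leaf, ] <<- geno
    rest <- idx[lens > D]
    if (length(rest)) {
      b <- substr(paths[rest], D + 1L, D + 1L)
      for (bb in unique(b)) recurse(rest[b == bb], D, geno)
    }
  }
  recurse(seq_along(paths), 0L, rep(0L, n_alleles))
  G
}

#' Mutate and measure a genealogy
#'
#' Applies the symmetric stepwise mutation process along the induced
#' genealogy (mutations on shared lineage segments are inherited jointly),
#' then emulates measurement: independent allelic dropout per cell and
#' allele, GV-stage multiallele events (flagged loci, excluded from
#' deviations as the analysis pipeline requires), and optional PCR repeat
#' cells (same true genotype, independent dropout).
#'
#' @param gen a `true_genealogy`.
#' @param scn the [sim_scenario()].
#' @param panel a `locus_panel` (defaults to `make_panel(scn$n_loci)`).
#' @param mouse_id,age_days metadata stamped on every cell.
#' @return list of [cell_signature()] objects.
#' @export
mutate_and_measure <- function(gen, scn, panel = make_panel(scn$n_loci),
                               mouse_id = "M1", age_days = 0L) {
  keys <- sort(c(allele_key(panel$locus_id, "A"),
                 allele_key(panel$locus_id, "B")))
  n_alleles <- length(keys)
  G <- sim_genotypes(gen$path, n_alleles, scn$mu, scn$p_plus)
  colnames(G) <- keys

  ids <- gen$cell_id
  meta <- gen
  if (scn$pcr_repeat_pairs > 0L) {
    pick <- sample.int(nrow(gen), min(scn$pcr_repeat_pairs, nrow(gen)))
    G <- rbind(G, G[pick, , drop = FALSE])
    rep_meta <- gen[pick, , drop = FALSE]
    rep_meta$cell_id <- paste0(gen$cell_id[pick], "_rep")
    meta <- rbind(gen, rep_meta)
    meta$pcr_repeat_of <- c(rep(NA_character_, nrow(gen)), gen$cell_id[pick])
  } else {
    meta$pcr_repeat_of <- NA_character_
  }

  lapply(seq_len(nrow(meta)), function(i) {
    observed <- runif(n_alleles) >= scn$dropout
    multi <- character(0)
    if (scn$gv_multiallele_rate > 0) {
      hit <- runif(scn$n_loci) < scn$gv_multiallele_rate
      multi <- panel$locus_id[hit]
      observed <- observed & !(key_locus(keys) %in% multi)
    }
    dev <- setNames(G[i, observed], keys[observed])
    cell_signature(
      cell_id = meta$cell_id[i], mouse_id = mouse_id, age_days = age_days,
      population = meta$population[i], deviations = dev,
      multiallelic_loci = multi, ovary_side = meta$ovary_side[i],
      plate_id = "P1", pcr_repeat_of = meta$pcr_repeat_of[i]
    )
  })
}

# per-cell depths for one mouse of age `age` under the scenario mode
scenario_depths <- function(scn, age, age_rank, n_ages) {
  switch(scn$mode,
    static = rep(scn$Td, scn$s),
    renewal = rep(scn$Td + as.integer(round(scn$renewal_rate * age / 100)),
                  scn$s),
    production_line = {
      # fixed birth-time depth distribution: uniform on [Td, Td + pl_span];
      # a mouse of age rank r samples its quantile band, except pre-antral
      # (young) mice which sample the full range
      if (age <= scn$pl_all_follicles_age) {
        u <- runif(scn$s)
      } else {
        u <- runif(scn$s, (age_rank - 1) / n_ages, age_rank / n_ages)
      }
      as.integer(scn$Td + round(u * scn$pl_span))
    },
    stop("unknown cohort mode: ", scn$mode)
  )
}

#' Simulate a multi-mouse cohort
#'
#' One genealogy and signature table per mouse (one mouse per entry of
#' `ages_days`). In `static` mode every mouse samples depth-`Td` oocytes; in
#' `renewal` mode oocyte depth grows with age through continued progenitor
#' divisions (`renewal_rate` divisions per 100 days); in `production_line`
#' mode each mouse samples the age-ranked quantile band of a fixed
#' birth-time depth distribution (young, pre-antral mice sample the whole
#' range).
#'
#' @param scn a [sim_scenario()] with `mode` in static/renewal/
#'   production_line and `ages_days` set.
#' @param include_other also sample the complement population per mouse.
#' @param panel locus panel shared by all mice.
#' @return list of `cell_signature` across all mice (mouse ids `"M<age>"`,
#'   made unique when ages repeat).
#' @export
scenario_cohort <- function(scn, include_other = FALSE,
                            panel = make_panel(scn$n_loci)) {
  if (!scn$mode %in% c("static", "renewal", "production_line")) {
    stop("scenario_cohort needs mode static, renewal or production_line")
  }
  ages <- scn$ages_days
  if (is.null(ages) || !length(ages)) stop("ages_days must be supplied")
  if (!is.null(scn$seed)) set.seed(scn$seed)
  ranks <- rank(ages, ties.method = "first")
  mouse_ids <- make.unique(sprintf("M%d", ages), sep = "_")
  cells <- list()
  for (i in seq_along(ages)) {
    depths <- scenario_depths(scn, ages[i], ranks[i], length(ages))
    gen <- simulate_genealogy(scn, depths = depths,
                              include_other = include_other)
    mcells <- mutate_and_measure(gen, scn, panel, mouse_id = mouse_ids[i],
                                 age_days = ages[i])
    # keep cell ids unique across mice
    mcells <- lapply(mcells, function(cl) {
      cl$cell_id <- paste(mouse_ids[i], cl$cell_id, sep = "_")
      cl
    })
    cells <- c(cells, mcells)
  }
  cells
}

#' Corrupt measured signals
#'
#' Adds +/-1 repeat errors to a stated fraction of the observed alleles,
#' emulating sizing errors; used for the estimator robustness runs.
#'
#' @param cells list of `cell_signature`.
#' @param rate fraction of observed alleles corrupted.
#' @return corrupted cells.
#' @export
corrupt_signals <- function(cells, rate = 0.1) {
  lapply(cells, function(cl) {
    n <- length(cl$deviations)
    if (!n) return(cl)
    hit <- runif(n) < rate
    cl$deviations[hit] <- cl$deviations[hit] +
      sample(c(-1L, 1L), sum(hit), replace = TRUE)
    cl
  })
}

#' Depth-estimator benchmark
#'
#' Compares the tree-ML depth readout (NJ on ML distances, median rooting)
#' with the squared-distance estimator (mean squared deviation from the
#' root, calibrated by `1/mu`) on simulated trees: bias (mean estimate minus
#' true depth), efficiency (SEM of the estimate over iterations), and
#' robustness to mutation-model deviations (`p_plus != 0.5`) and to signal
#' errors (random +/-1 corruption of a fraction of alleles).
#'
#' @param Td_values true tree depths to benchmark.
#' @param n_iter sampling iterations per depth.
#' @param scn base scenario (cells per iteration, panel size, mu, dropout).
#' @param p_plus step asymmetry used by the generator.
#' @param signal_error_rate fraction of observed alleles corrupted.
#' @param seed RNG seed.
#' @return data.frame: `estimator`, `Td`, `mean_estimate`, `bias`, `sem`.
#' @export
estimator_benchmark <- function(Td_values = c(25L, 45L), n_iter = 50L,
                                scn = sim_scenario(), p_plus = 0.5,
                                signal_error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- stepwise_model(mu = scn$mu)
  panel <- make_panel(scn$n_loci)
  rows <- list()
  for (Td in Td_values) {
    scn_td <- scn
    scn_td$Td <- as.integer(Td)
    scn_td$p_plus <- p_plus
    est_tree <- numeric(n_iter)
    est_sq <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      gen <- simulate_genealogy(scn_td, restrict = FALSE)
      cells <- mutate_and_measure(gen, scn_td, panel)
      if (signal_error_rate > 0) {
        cells <- corrupt_signals(cells, signal_error_rate)
      }
      rec <- reconstruct_tree(cells, model)
      est_tree[it] <- median(rec$depths)
      est_sq[it] <- median(vapply(cells, squared_distance_depth,
                                  numeric(1), root = rec$root,
                                  scale = 1 / scn$mu))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = c("tree_ml", "squared_distance"), Td = Td,
      mean_estimate = c(mean(est_tree), mean(est_sq)),
      bias = c(mean(est_tree) - Td, mean(est_sq) - Td),
      sem = c(sd(est_tree), sd(est_sq)) / sqrt(n_iter),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Progenitor-number power study
#'
#' For each progenitor count `Np`, simulates `n_trees` genealogies (focal
#' population restricted to `Np` progenitors at division `Tr`, plus an equal
#' complement sample), runs the full reconstruction + enrichment pipeline,
#' and reports the fraction of trees in which the focal population clusters.
#' Detection power falls as `Np` approaches the sample size, which is what
#' bounds the progenitor number of a real population.
#'
#' @param Np_grid progenitor counts to scan.
#' @param s cells per population.
#' @param n_trees trees per grid point.
#' @param q FDR level for detection (0.05 as in the simulation studies).
#' @param scn base scenario.
#' @param seed RNG seed.
#' @return data.frame: `Np`, `detection_fraction`, `se`, `n_trees`.
#' @export
progenitor_power_study <- function(Np_grid = c(2L, 4L, 8L, 16L, 30L),
                                   s = 30L, n_trees = 50L, q = 0.05,
                                   scn = sim_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- stepwise_model(mu = scn$mu)
  panel <- make_panel(scn$n_loci)
  rows <- lapply(Np_grid, function(np) {
    scn_np <- scn
    scn_np$Np <- as.integer(np)
    scn_np$s <- as.integer(s)
    hits <- vapply(seq_len(n_trees), function(i) {
      gen <- simulate_genealogy(scn_np, include_other = TRUE)
      cells <- mutate_and_measure(gen, scn_np, panel)
      rec <- reconstruct_tree(cells, model)
      labels <- setNames(gen$population, gen$cell_id)
      as.logical(clustering_detected(rec$tree, labels, "oocyte", q))
    }, logical(1))
    p <- mean(hits)
    data.frame(Np = np, detection_fraction = p,
               se = sqrt(p * (1 - p) / n_trees), n_trees = n_trees)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Clustering power by subsampling an existing cohort
#'
#' Companion to [progenitor_power_study()]: repeatedly subsamples `s`
#' cells of the focal population and `s` of the complement from a measured
#' (or simulated) cohort, reconstructs the tree, and reports the fraction of
#' iterations with detected clustering.
#'
#' @param cells list of `cell_signature` for one mouse.
#' @param sizes subsample sizes to scan.
#' @param population focal population.
#' @param n_iter iterations per size.
#' @param q FDR level.
#' @param model a [stepwise_model()].
#' @param seed RNG seed.
#' @return data.frame: `s`, `detection_fraction`, `se`, `n_iter`.
#' @export
subsample_power <- function(cells, sizes, population = "oocyte",
                            n_iter = 30L, q = 0.05,
                            model = stepwise_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- vapply(cells, `[[`, character(1), "population")
  focal <- which(pops == population)
  rest <- which(pops != population)
  rows <- lapply(sizes, function(sz) {
    if (sz > length(focal) || sz > length(rest)) {
      stop("subsample size exceeds available cells")
    }
    hits <- vapply(seq_len(n_iter), function(i) {
      sub <- cells[c(sample(focal, sz), sample(rest, sz))]
      rec <- reconstruct_tree(sub, model)
      labels <- setNames(vapply(sub, `[[`, character(1), "population"),
                         vapply(sub, `[[`, character(1), "cell_id"))
      as.logical(clustering_detected(rec$tree, labels, population, q))
    }, logical(1))
    p <- mean(hits)
    data.frame(s = sz, detection_fraction = p,
               se = sqrt(p * (1 - p) / n_iter), n_iter = n_iter)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
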
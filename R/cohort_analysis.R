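# Cohort-level statistics: depth vs age, ovariectomy contrasts, the
# production-line resampling test, spontaneous-mutation tallies and the
# mutation-rate sensitivity sweep.

#' Per-mouse depth summaries
#'
#' Runs the full reconstruction pipeline separately for each mouse and
#' summarizes the depths of one population (median and SEM), the unit of the
#' depth-versus-age analyses.
#'
#' @param cells list of `cell_signature` (possibly several mice).
#' @param model a [stepwise_model()].
#' @param population population whose depths are summarized.
#' @return data.frame: `mouse_id`, `age_days`, `n_cells`, `median_depth`,
#'   `sem`; attribute `"cell_depths"` holds the per-mouse depth vectors.
#' @export
cohort_depth_summaries <- function(cells, model = stepwise_model(),
                                   population = "oocyte") {
  mice <- vapply(cells, `[[`, character(1), "mouse_id")
  out <- list()
  depth_list <- list()
  for (m in unique(mice)) {
    sub <- cells[mice == m]
    rec <- reconstruct_tree(sub, model)
    pops <- setNames(vapply(sub, `[[`, character(1), "population"),
                     vapply(sub, `[[`, character(1), "cell_id"))
    ids <- names(pops)[pops == population]
    d <- rec$depths[intersect(names(rec$depths), ids)]
    depth_list[[m]] <- d
    out[[m]] <- data.frame(
      mouse_id = m, age_days = sub[[1]]$age_days, n_cells = length(d),
      median_depth = median(d), sem = sd(d) / sqrt(length(d)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cell_depths") <- depth_list
  res
}

#' Depth-age correlation with permutation p-value
#'
#' Pearson correlation of per-mouse median depth against age, with a
#' one-sided (positive trend) permutation p-value obtained by shuffling the
#' median depths across mice: `p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`,
#' which never returns exactly zero.
#'
#' @param summaries data.frame with columns `age_days` and `median_depth`
#'   (as from [cohort_depth_summaries()]), >= 3 mice.
#' @param n_perm number of permutations (>= 100).
#' @return list with `R` and `p_perm`; both `NA` (with a warning) when the
#'   medians are constant.
#' @export
depth_age_correlation <- function(summaries, n_perm = 1000L) {
  stopifnot(nrow(summaries) >= 3, n_perm >= 100)
  age <- summaries$age_days
  med <- summaries$median_depth
  if (sd(med) == 0 || sd(age) == 0) {
    warning("constant medians or ages: correlation undefined")
    return(list(R = NA_real_, p_perm = NA_real_))
  }
  R <- cor(age, med)
  R_perm <- vapply(seq_len(n_perm),
                   function(i) cor(age, sample(med)), numeric(1))
  list(R = R, p_perm = (1 + sum(R_perm >= R)) / (1 + n_perm))
}

#' Bootstrap correlation of median depth and age
#'
#' Per replicate, each mouse's cell depths are resampled with replacement,
#' medians recomputed and the Pearson correlation with age taken; the mean
#' over replicates is the bootstrap correlation (the study used 1000
#' replicates).
#'
#' @param cell_depths named list (mouse -> numeric depth vector), each with
#'   >= 2 cells.
#' @param ages numeric vector of ages aligned with `cell_depths`.
#' @param n_boot replicates.
#' @return list with `R_boot_mean` and the replicate vector `R_boot`.
#' @export
bootstrap_correlation <- function(cell_depths, ages, n_boot = 1000L) {
  stopifnot(length(cell_depths) == length(ages),
            all(lengths(cell_depths) >= 2))
  R_boot <- vapply(seq_len(n_boot), function(i) {
    med <- vapply(cell_depths,
                  function(d) median(sample(d, replace = TRUE)), numeric(1))
    if (sd(med) == 0) return(NA_real_)
    cor(ages, med)
  }, numeric(1))
  list(R_boot_mean = mean(R_boot, na.rm = TRUE), R_boot = R_boot)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param depths_a,depths_b numeric vectors (>= 3 values each).
#' @return list with statistic `D` and asymptotic `p`.
#' @export
ks_compare <- function(depths_a, depths_b) {
  stopifnot(length(depths_a) >= 3, length(depths_b) >= 3)
  kt <- suppressWarnings(ks.test(depths_a, depths_b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Ovariectomy depth contrast
#'
#' Compares oocyte depths from the ovary removed young against the
#' contralateral ovary removed months later in the same mouse: median
#' difference (old - young), the KS p-value, and arm means with SEM.
#'
#' @param young,old numeric depth vectors (non-empty).
#' @return list with `median_diff`, `ks`, `mean_young`, `mean_old`,
#'   `sem_young`, `sem_old`.
#' @export
ovariectomy_contrast <- function(young, old) {
  stopifnot(length(young) > 0, length(old) > 0)
  list(median_diff = median(old) - median(young),
       ks = ks_compare(young, old),
       mean_young = mean(young), mean_old = mean(old),
       sem_young = sd(young) / sqrt(length(young)),
       sem_old = sd(old) / sqrt(length(old)))
}

#' Production-line resampling test
#'
#' Builds a putative birth depth distribution by weighting the depth values
#' observed at each age equally (uniform weight per age group, not per cell),
#' draws samples of the young cohort's size from it, and reports the fraction
#' of simulations whose statistic (median or max) is smaller than the
#' observed young statistic. Under the production-line hypothesis the
#' youngest mice sample the shallow end of a wide pre-existing distribution,
#' so small p rejects compatibility. Both tails are returned; `p` is the
#' "smaller" direction.
#'
#' @param depths_by_age named list (age -> depth vector), >= 2 ages.
#' @param young_observed depths observed in the young (12-day) mouse.
#' @param n_sim number of simulations (>= 1000).
#' @param statistic `"median"` or `"max"`.
#' @return list with `p` (= `p_smaller`), `p_larger`, `observed`, `statistic`.
#' @export
production_line_test <- function(depths_by_age, young_observed,
                                 n_sim = 1000L, statistic = c("median", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(length(depths_by_age) >= 2, n_sim >= 1000)
  if (!length(young_observed)) stop("young sample is empty")
  stat_fun <- if (statistic == "median") median else max
  obs <- stat_fun(young_observed)
  n_draw <- length(young_observed)
  # equal weight per age group: pick a group uniformly, then a value within it
  lens <- lengths(depths_by_age)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  pool <- unlist(depths_by_age, use.names = FALSE)
  groups <- sample.int(length(depths_by_age), n_sim * n_draw, replace = TRUE)
  within <- floor(runif(n_sim * n_draw) * lens[groups]) + 1L
  sims <- matrix(pool[offs[groups] + within], nrow = n_sim)
  sim_stat <- apply(sims, 1L, stat_fun)
  list(p = mean(sim_stat < obs), p_smaller = mean(sim_stat < obs),
       p_larger = mean(sim_stat > obs), observed = obs, statistic = statistic)
}

#' Fisher combination of p-values
#'
#' `X = -2 * sum(log p)` referred to a chi-square distribution with `2k`
#' degrees of freedom. Zero p-values are clipped to the smallest positive
#' double with a warning.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
fisher_combine <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values >= 0), all(p_values <= 1))
  if (any(p_values == 0)) {
    warning("p-value of 0 clipped to the smallest representable positive")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  X <- -2 * sum(log(p_values))
  pchisq(X, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Spontaneous versus replication-dependent mutation tally
#'
#' GV oocytes carry four chromatid copies per locus, so a spontaneous
#' (replication-independent) mutation during meiotic arrest mostly yields a
#' locus with more than two alleles, whereas replication-dependent mutations
#' at the two-copy progenitor stage yield at most two. Per mouse, this
#' tallies flagged multiallelic loci (spontaneous candidates) against the
#' total number of observed mutations (alleles deviating from the root).
#'
#' @param cells list of `cell_signature`.
#' @param root a `root_signature` (typically per mouse; a shared root is
#'   accepted).
#' @return data.frame per mouse: `mouse_id`, `age_days`,
#'   `n_multiallelic_loci`, `n_total_mutations`, `n_alleles_observed`,
#'   `fraction_spontaneous`, `fraction_replication`.
#' @export
spontaneous_mutation_tally <- function(cells, root) {
  mice <- vapply(cells, `[[`, character(1), "mouse_id")
  rows <- lapply(unique(mice), function(m) {
    sub <- cells[mice == m]
    n_multi <- sum(vapply(sub, function(cl) length(cl$multiallelic_loci),
                          integer(1)))
    n_mut <- 0L
    n_obs <- 0L
    for (cl in sub) {
      shared <- intersect(names(cl$deviations), names(root$deviations))
      n_obs <- n_obs + length(shared)
      n_mut <- n_mut + sum(cl$deviations[shared] != root$deviations[shared])
    }
    data.frame(mouse_id = m, age_days = sub[[1]]$age_days,
               n_multiallelic_loci = n_multi, n_total_mutations = n_mut,
               n_alleles_observed = n_obs,
               fraction_spontaneous = if (n_obs) n_multi / n_obs else 0,
               fraction_replication = if (n_obs) n_mut / n_obs else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mutation-rate sensitivity sweep
#'
#' Rebuilds distances, trees and depths for each assumed mutation rate and
#' reports the sign of the depth-age correlation and the fraction of mice in
#' which the focal population clusters -- the conclusions should be invariant
#' across rates between 1/10 and 1/200 per division.
#'
#' @param cells list of `cell_signature` (several mice, with population
#'   labels).
#' @param rates vector of per-allele per-division rates.
#' @param population focal population for clustering detection.
#' @param q FDR level for the clustering detection.
#' @param n_perm permutations for the depth-age p-value.
#' @return data.frame per rate: `mu`, `R`, `R_positive`, `p_perm`,
#'   `clustering_fraction` (share of mice with >= 2 populations in which the
#'   focal population clusters).
#' @export
mutation_rate_sweep <- function(cells, rates = 1 / c(10, 30, 100, 200),
                                population = "oocyte", q = 0.2,
                                n_perm = 1000L) {
  if (!length(rates)) {
    return(data.frame(mu = numeric(), R = numeric(), R_positive = logical(),
                      p_perm = numeric(), clustering_fraction = numeric()))
  }
  mice <- vapply(cells, `[[`, character(1), "mouse_id")
  rows <- lapply(rates, function(mu) {
    model <- stepwise_model(mu = mu)
    det <- c()
    summaries <- list()
    for (m in unique(mice)) {  # one reconstruction per mouse, reused for both
      sub <- cells[mice == m]
      pops <- setNames(vapply(sub, `[[`, character(1), "population"),
                       vapply(sub, `[[`, character(1), "cell_id"))
      rec <- reconstruct_tree(sub, model)
      d <- rec$depths[names(pops)[pops == population]]
      summaries[[m]] <- data.frame(mouse_id = m,
                                   age_days = sub[[1]]$age_days,
                                   median_depth = median(d))
      if (length(unique(pops)) >= 2L) {
        det <- c(det, as.logical(clustering_detected(rec$tree, pops,
                                                     population, q)))
      }
    }
    da <- depth_age_correlation(do.call(rbind, summaries), n_perm)
    data.frame(mu = mu, R = da$R, R_positive = !is.na(da$R) && da$R > 0,
               p_perm = da$p_perm,
               clustering_fraction = if (length(det)) mean(det) else NA_real_)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
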
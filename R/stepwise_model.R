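#' Symmetric stepwise mutation model
#'
#' Each division, each allele mutates with probability `mu`; a mutation
#' changes the repeat count by +1 or -1 with equal probability. `mu` is
#' interpreted per allele per division (the two parental alleles of a locus
#' mutate independently); the calibration rate estimated ex vivo is 1/30.
#' `t_max` bounds the maximum-likelihood search over division separations.
#'
#' @param mu per-allele per-division mutation probability, in (0, 1).
#' @param t_max largest division count considered in the ML search.
#' @param min_overlap minimum shared observed alleles for a pairwise distance
#'   to be defined.
#' @return object of class `stepwise_model`.
#' @export
stepwise_model <- function(mu = 1 / 30, t_max = 500L, min_overlap = 10L) {
  if (!(is.numeric(mu) && length(mu) == 1 && mu > 0 && mu < 1)) {
    stop("mu must be a single value in (0, 1)")
  }
  t_max <- as.integer(t_max)
  if (t_max < 1L) stop("t_max must be >= 1")
  structure(list(mu = mu, t_max = t_max,
                 min_overlap = as.integer(min_overlap)),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> mu = %.5g (1/%.3g), t_max = %d, min_overlap = %d\n",
              x$mu, 1 / x$mu, x$t_max, x$min_overlap))
  invisible(x)
}

# pmf table of the net repeat change under the symmetric stepwise model.
# Row t+1, column d+1 holds P(net change = d | t divisions) for d = 0..t_max;
# by symmetry P(net = -d) = P(net = d). Computed by dynamic programming over
# (division, net step) on the full lattice |net| <= t_max, so entries are
# exact (no truncation leak) for every t <= t_max. Memoized per (mu, t_max).
stepwise_pmf_table <- function(mu, t_max) {
  key <- sprintf("%.17g|%d", mu, t_max)
  hit <- get0(key, envir = .pmf_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  width <- 2L * t_max + 1L
  centre <- t_max + 1L
  v <- numeric(width)
  v[centre] <- 1
  tab <- matrix(0, nrow = t_max + 1L, ncol = t_max + 1L)
  tab[1L, 1L] <- 1
  half <- mu / 2
  stay <- 1 - mu
  for (t in seq_len(t_max)) {
    left <- c(v[-1L], 0)
    right <- c(0, v[-width])
    v <- stay * v + half * (left + right)
    tab[t + 1L, ] <- v[centre:width]
  }
  assign(key, tab, envir = .pmf_cache)
  tab
}

#' Probability of a net repeat-size difference after t divisions
#'
#' `P(net change = delta | t divisions)` under the symmetric stepwise model:
#' the number of mutations is Binomial(t, mu) and each mutation is an
#' independent +/-1 step, so the net change is a lazy random walk. This pmf is
#' the kernel of every likelihood in the package.
#'
#' @param delta integer net repeat difference(s); vectorized.
#' @param t non-negative integer number of divisions.
#' @param mu per-allele per-division mutation probability.
#' @return numeric vector of probabilities.
#' @export
step_diff_pmf <- function(delta, t, mu) {
  t <- as.integer(t)
  if (is.na(t) || t < 0) stop("t must be a non-negative integer")
  delta <- as.integer(delta)
  if (t == 0L) return(as.numeric(delta == 0L))
  tab <- stepwise_pmf_table(mu, t)
  out <- numeric(length(delta))
  inside <- abs(delta) <= t
  out[inside] <- tab[t + 1L, abs(delta[inside]) + 1L]
  out
}

# log pmf table rows t=0..t_max, cols |delta|=0..d_max, with zeros floored to
# keep -Inf out of likelihood sums (a floored cell is ~exp(-708) per allele,
# far below any feasible likelihood, so argmax is unaffected).
stepwise_logpmf <- function(model, d_max) {
  tab <- stepwise_pmf_table(model$mu, model$t_max)
  sub <- tab[, seq_len(d_max + 1L), drop = FALSE]
  log(pmax(sub, .Machine$double.xmin))
}

#' Maximum-likelihood division distance between two cells
#'
#' The number of divisions separating two cells is estimated as the integer
#' `t` in `[0, t_max]` maximizing the log likelihood of the observed per-allele
#' repeat differences under the stepwise model, using only alleles observed
#' in both cells (pairwise-complete; no imputation). Ties take the smallest
#' `t` (parsimony). Pairs sharing fewer than `min_overlap` alleles are
#' undefined: `t_hat` is `NA`, distinct from a genuine zero distance.
#'
#' @param a,b `cell_signature` or `root_signature` objects.
#' @param model a [stepwise_model()].
#' @return list with `t_hat` (integer or `NA`) and `overlap` (shared alleles).
#' @export
ml_pairwise_distance <- function(a, b, model = stepwise_model()) {
  shared <- intersect(names(a$deviations), names(b$deviations))
  overlap <- length(shared)
  if (overlap < model$min_overlap) {
    return(list(t_hat = NA_integer_, overlap = overlap))
  }
  d <- abs(a$deviations[shared] - b$deviations[shared])
  list(t_hat = ml_t_from_counts(tabulate(d + 1L), model), overlap = overlap)
}

# counts[k] = number of shared alleles with |delta| = k-1
ml_t_from_counts <- function(counts, model) {
  d_max <- length(counts) - 1L
  if (d_max > model$t_max) stop("observed |delta| exceeds t_max")
  lp <- stepwise_logpmf(model, d_max)
  ll <- as.vector(lp %*% counts)
  as.integer(which.max(ll) - 1L)  # which.max takes the first (smallest t)
}

#' Pairwise ML distance matrix for a cohort
#'
#' Computes all pairwise ML division distances among cells, plus each cell's
#' distance to the root pseudo-cell (labelled `"root_median"`), which
#' participates in neighbor joining as a taxon. Cell order is canonicalized
#' by sorted `cell_id` so downstream reconstruction is deterministic.
#'
#' @param cells list of `cell_signature` (>= 3 after QC).
#' @param root a `root_signature` from [compute_root_signature()]; treated as
#'   a complete signature (no missing alleles).
#' @param model a [stepwise_model()].
#' @return object of class `ms_dist`: list with `labels`, symmetric numeric
#'   matrix `d` (divisions, zero diagonal) and integer matrix `overlap`.
#' @export
build_distance_matrix <- function(cells, root, model = stepwise_model()) {
  if (length(cells) < 3L) stop("need >= 3 cells after QC")
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) stop("duplicate cell_id")
  cells <- cells[order(ids)]
  ids <- sort(ids)
  if ("root_median" %in% ids) stop("'root_median' is a reserved label")
  sigs <- c(lapply(cells, `[[`, "deviations"), list(root$deviations))
  labels <- c(ids, "root_median")
  n <- length(labels)

  # cells x alleles deviation matrix (NA = dropout); root row complete
  keys <- sort(unique(unlist(lapply(sigs, names))))
  D <- matrix(NA_integer_, nrow = n, ncol = length(keys),
              dimnames = list(labels, keys))
  for (i in seq_len(n)) D[i, names(sigs[[i]])] <- sigs[[i]]

  dmat <- matrix(0, n, n, dimnames = list(labels, labels))
  omat <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(omat) <- rowSums(!is.na(D))

  pair_counts <- vector("list", n * (n - 1L) / 2L)
  overlaps <- integer(length(pair_counts))
  d_max <- 0L
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      dd <- abs(D[i, ] - D[j, ])
      dd <- dd[!is.na(dd)]
      overlaps[k] <- length(dd)
      if (length(dd)) {
        pair_counts[[k]] <- tabulate(dd + 1L, nbins = max(dd) + 1L)
        d_max <- max(d_max, max(dd))
      } else pair_counts[[k]] <- integer(0)
    }
  }
  bad <- overlaps < model$min_overlap
  if (any(bad)) {
    pairs <- t(combn(labels, 2L))[bad, , drop = FALSE]
    stop("pairwise distance undefined (overlap < ", model$min_overlap,
         ") for: ", paste(apply(pairs, 1, paste, collapse = " ~ "),
                          collapse = ", "))
  }
  if (d_max > model$t_max) stop("observed |delta| exceeds t_max")
  lp <- stepwise_logpmf(model, d_max)
  cmat <- matrix(0, nrow = length(pair_counts), ncol = d_max + 1L)
  for (k in seq_along(pair_counts)) {
    cmat[k, seq_along(pair_counts[[k]])] <- pair_counts[[k]]
  }
  ll <- cmat %*% t(lp)                      # pairs x (t_max+1)
  t_hat <- max.col(ll, ties.method = "first") - 1L
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      dmat[i, j] <- dmat[j, i] <- t_hat[k]
      omat[i, j] <- omat[j, i] <- overlaps[k]
    }
  }
  structure(list(labels = labels, d = dmat, overlap = omat),
            class = "ms_dist")
}

#' @export
print.ms_dist <- function(x, ...) {
  cat(sprintf("<ms_dist> %d taxa (incl. root_median), mean distance %.1f divisions\n",
              length(x$labels), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Serialize a distance matrix
#'
#' Writes the square distance matrix either as a PHYLIP square matrix
#' (`format = "phylip"`) or as a labelled TSV (`format = "tsv"`).
#'
#' @param dm an `ms_dist`.
#' @param path output path.
#' @param format `"phylip"` or `"tsv"`.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$labels)), con)
    for (i in seq_along(dm$labels)) {
      writeLines(paste(c(formatC(dm$labels[i], width = -10),
                         sprintf("%.6f", dm$d[i, ])), collapse = "  "), con)
    }
  } else {
    write.table(dm$d, path, sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Estimate the mutation rate from cells of known depth
#'
#' Ex-vivo style calibration: given cells whose true division depth is known
#' and the root signature, the per-allele per-division rate is the maximizer
#' of the stepwise log likelihood of the root-to-cell repeat differences. The
#' likelihood is scanned on a log-spaced grid and refined by golden-section
#' search around the best grid point.
#'
#' @param cells list of `cell_signature` (>= 2).
#' @param depths integer vector of known depths (divisions, >= 1), one per cell.
#' @param root a `root_signature`.
#' @param grid log-spaced candidate rates.
#' @return `mu_hat`, the estimated rate.
#' @export
estimate_mutation_rate <- function(cells, depths, root,
                                   grid = exp(seq(log(1e-3), log(0.5),
                                                  length.out = 60))) {
  stopifnot(length(cells) == length(depths), length(cells) >= 2,
            all(depths >= 1))
  depths <- as.integer(depths)
  # per distinct depth, pooled |delta| counts against the root
  counts <- list()
  for (i in seq_along(cells)) {
    shared <- intersect(names(cells[[i]]$deviations), names(root$deviations))
    d <- abs(cells[[i]]$deviations[shared] - root$deviations[shared])
    key <- as.character(depths[i])
    cc <- tabulate(d + 1L, nbins = max(d, 0L) + 1L)
    old <- counts[[key]]
    if (is.null(old)) counts[[key]] <- cc
    else {
      m <- max(length(old), length(cc))
      counts[[key]] <- c(old, rep(0, m - length(old))) +
        c(cc, rep(0, m - length(cc)))
    }
  }
  loglik <- function(mu) {
    sum(vapply(names(counts), function(key) {
      t <- as.integer(key)
      cc <- counts[[key]]
      lp <- log(pmax(step_diff_pmf(seq_along(cc) - 1L, t, mu),
                     .Machine$double.xmin))
      sum(lp * cc)
    }, numeric(1)))
  }
  ll <- vapply(grid, loglik, numeric(1))
  best <- which.max(ll)
  if (best == 1L) {
    warning("likelihood maximized at the lower grid bound (no mutations?)")
    return(grid[1L])
  }
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-6)$maximum
}

#' Squared-distance depth statistic
#'
#' The comparison estimator for depth: the mean squared repeat deviation of a
#' cell from the root over shared alleles, on the raw squared-step scale.
#' Its expectation is `mu * depth`, so dividing by an externally calibrated
#' rate (`scale = 1/mu`) converts to divisions; the default `scale = 1`
#' returns the raw statistic.
#'
#' @param cell a `cell_signature`.
#' @param root a `root_signature`.
#' @param scale linear calibration factor applied to the mean square.
#' @return numeric depth statistic.
#' @export
squared_distance_depth <- function(cell, root, scale = 1) {
  shared <- intersect(names(cell$deviations), names(root$deviations))
  if (!length(shared)) stop("no alleles shared with the root")
  mean((cell$deviations[shared] - root$deviations[shared])^2) * scale
}
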
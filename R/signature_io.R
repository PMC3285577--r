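#' Microsatellite locus panel
#'
#' Constructs (or validates) a locus panel table. Each locus is diploid with
#' two strain-distinguishable reference alleles: the mouse strains are crossed
#' so that at every locus the two parental alleles differ substantially in
#' repeat number and can never be confounded when sizing fragments.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param repeat_unit_len integer repeat-unit length in bases (1 or 2 typical).
#' @param allele_a_ref_size integer reference repeat count, strain-1 allele.
#' @param allele_b_ref_size integer reference repeat count, strain-2 allele.
#' @return A `data.frame` of class `locus_panel`.
#' @export
locus_panel <- function(locus_id, repeat_unit_len, allele_a_ref_size,
                        allele_b_ref_size) {
  if (anyDuplicated(locus_id)) stop("duplicate locus_id in panel")
  if (any(allele_a_ref_size == allele_b_ref_size)) {
    stop("panel loci must have distinct strain reference sizes")
  }
  panel <- data.frame(
    locus_id = as.character(locus_id),
    repeat_unit_len = as.integer(repeat_unit_len),
    allele_a_ref_size = as.integer(allele_a_ref_size),
    allele_b_ref_size = as.integer(allele_b_ref_size),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("locus_panel", "data.frame")
  panel
}

#' Default synthetic locus panel
#'
#' A panel of `n_loci` dinucleotide/mononucleotide loci with well-separated
#' strain reference sizes, mirroring the design requirement that the two
#' parental alleles never overlap in size.
#'
#' @param n_loci number of loci (default 81, the study panel size).
#' @return A `locus_panel`.
#' @export
make_panel <- function(n_loci = 81L) {
  i <- seq_len(n_loci)
  locus_panel(
    locus_id = sprintf("L%03d", i),
    repeat_unit_len = rep_len(c(1L, 2L), n_loci),
    allele_a_ref_size = 20L + (i %% 11L),
    allele_b_ref_size = 20L + (i %% 11L) + 12L
  )
}

#' @rdname locus_panel
#' @param path file path of a panel TSV (columns `locus_id`,
#'   `repeat_unit_len`, `allele_a_ref_size`, `allele_b_ref_size`).
#' @export
read_panel <- function(path) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("locus_id", "repeat_unit_len", "allele_a_ref_size",
            "allele_b_ref_size")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("panel file missing columns: ",
                         paste(miss, collapse = ", "))
  locus_panel(x$locus_id, x$repeat_unit_len, x$allele_a_ref_size,
              x$allele_b_ref_size)
}

#' @rdname locus_panel
#' @param panel a `locus_panel`.
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

allele_key <- function(locus_id, parental) paste(locus_id, parental, sep = "|")

key_locus <- function(keys) sub("\\|[AB]$", "", keys)

#' Single-cell microsatellite signature
#'
#' A cell's genomic signature: per-allele repeat-count deviations from the
#' locus reference, plus sample metadata. Alleles are keyed
#' `"<locus_id>|<A|B>"` (parental A = strain-1 allele, B = strain-2).
#' Missing alleles (allelic dropout) are simply absent from `deviations`.
#' Loci at which the capillary signal showed more than two alleles are
#' recorded in `multiallelic_loci` and carry no deviations: such signals
#' indicate a mutation at the four-chromatid GV stage and are excluded from
#' all distance computations.
#'
#' @param cell_id,mouse_id identifiers.
#' @param age_days mouse age in days (non-negative integer).
#' @param population one of `"oocyte"`, `"lymphocyte"`, `"msc"`, `"cumulus"`,
#'   `"islet"`, `"other"`.
#' @param deviations named integer vector of repeat-step deviations, names
#'   are allele keys.
#' @param multiallelic_loci character vector of locus ids flagged >2 alleles.
#' @param ovary_side optional `"left"`/`"right"`.
#' @param follicle_id,plate_id,pcr_repeat_of optional identifiers.
#' @return An object of class `cell_signature`.
#' @export
cell_signature <- function(cell_id, mouse_id, age_days, population,
                           deviations = integer(),
                           multiallelic_loci = character(),
                           ovary_side = NA_character_,
                           follicle_id = NA_character_,
                           plate_id = NA_character_,
                           pcr_repeat_of = NA_character_) {
  population <- match.arg(population,
                          c("oocyte", "lymphocyte", "msc", "cumulus",
                            "islet", "other"))
  if (!is.na(ovary_side)) {
    ovary_side <- match.arg(ovary_side, c("left", "right"))
  }
  age_days <- as.integer(age_days)
  if (is.na(age_days) || age_days < 0) stop("age_days must be >= 0")
  deviations <- deviations[order(names(deviations))]
  storage.mode(deviations) <- "integer"
  loci <- key_locus(names(deviations))
  if (length(loci) && max(table(loci)) > 2L) {
    stop("more than 2 deviation entries for a locus in cell ", cell_id)
  }
  multiallelic_loci <- sort(unique(as.character(multiallelic_loci)))
  if (length(intersect(multiallelic_loci, loci))) {
    stop("multiallelic loci must not carry deviations (cell ", cell_id, ")")
  }
  structure(
    list(cell_id = as.character(cell_id), mouse_id = as.character(mouse_id),
         age_days = age_days, population = population,
         ovary_side = ovary_side, follicle_id = as.character(follicle_id),
         plate_id = as.character(plate_id),
         pcr_repeat_of = as.character(pcr_repeat_of),
         deviations = deviations, multiallelic_loci = multiallelic_loci),
    class = "cell_signature"
  )
}

#' @export
print.cell_signature <- function(x, ...) {
  cat(sprintf("<cell_signature> %s (%s, %s, %d d): %d alleles, %d multiallelic loci\n",
              x$cell_id, x$mouse_id, x$population, x$age_days,
              length(x$deviations), length(x$multiallelic_loci)))
  invisible(x)
}

#' Assign an observed allele size to a parental allele
#'
#' The strains are chosen so that allele sizes never confound; assignment is
#' by proximity to the two strain reference sizes. An exact midpoint cannot
#' be attributed to either parent and returns `NA` (the locus should then be
#' dropped for that cell) -- this only fires on corrupt input.
#'
#' @param repeat_size observed repeat count(s).
#' @param locus one row of a `locus_panel`.
#' @return character vector of `"A"`, `"B"` or `NA`.
#' @export
assign_parental <- function(repeat_size, locus) {
  da <- abs(repeat_size - locus$allele_a_ref_size)
  db <- abs(repeat_size - locus$allele_b_ref_size)
  out <- ifelse(da < db, "A", ifelse(db < da, "B", NA_character_))
  out
}

.sig_columns <- c("cell_id", "mouse_id", "age_days", "population",
                  "ovary_side", "follicle_id", "plate_id", "pcr_repeat_of",
                  "locus_id", "parental", "deviation", "multiallelic_flag")

#' Read a signature table
#'
#' Reads the tidy per-allele TSV dialect: one row per (cell, locus, parental
#' allele), columns `cell_id`, `mouse_id`, `age_days`, `population`,
#' `ovary_side`, `follicle_id`, `plate_id`, `pcr_repeat_of`, `locus_id`,
#' `parental`, `deviation`, `multiallelic_flag`. Rows with a truthy
#' `multiallelic_flag` mark the locus as showing more than two alleles; the
#' locus is excluded from the cell's deviations. If `parental` is blank and a
#' `repeat_size` column is present, the parental allele is assigned by
#' proximity to the strain reference sizes and the deviation computed from
#' the matching reference.
#'
#' @param path TSV file path.
#' @param panel the `locus_panel`; every `locus_id` in the file must belong
#'   to it.
#' @return list of [cell_signature()] objects, one per distinct `cell_id` in
#'   file order.
#' @export
read_signature_table <- function(path, panel) {
  if (file.size(path) == 0) return(list())
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  miss <- setdiff(setdiff(.sig_columns, c("deviation")), names(x))
  if (length(miss)) stop("signature table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(list())
  bad <- setdiff(unique(x$locus_id), panel$locus_id)
  if (length(bad)) stop("unknown locus_id not in panel: ",
                        paste(bad, collapse = ", "))
  flag <- tolower(trimws(x$multiallelic_flag)) %in% c("1", "true", "yes")
  has_size <- "repeat_size" %in% names(x)

  cells <- list()
  for (cid in unique(x$cell_id)) {
    rows <- which(x$cell_id == cid)
    sub <- x[rows, , drop = FALSE]
    multi <- unique(sub$locus_id[flag[rows]])
    keep <- !flag[rows] & !(sub$locus_id %in% multi)
    dev <- integer(0)
    keys <- character(0)
    for (j in which(keep)) {
      row_no <- rows[j] + 1L  # +1 for the header line
      loc <- panel[panel$locus_id == sub$locus_id[j], , drop = FALSE]
      par <- trimws(sub$parental[j])
      d <- suppressWarnings(as.integer(sub$deviation[j]))
      if ((is.na(par) || par == "") && has_size) {
        size <- suppressWarnings(as.numeric(sub$repeat_size[j]))
        if (is.na(size)) stop("malformed repeat_size at line ", row_no)
        par <- assign_parental(size, loc)
        if (is.na(par)) next  # ambiguous midpoint: drop locus for this cell
        ref <- if (par == "A") loc$allele_a_ref_size else loc$allele_b_ref_size
        d <- as.integer(size - ref)
      }
      if (is.na(par) || !(par %in% c("A", "B"))) {
        stop("malformed parental value at line ", row_no)
      }
      if (is.na(d)) stop("malformed deviation at line ", row_no)
      keys <- c(keys, allele_key(sub$locus_id[j], par))
      dev <- c(dev, d)
    }
    if (anyDuplicated(keys)) {
      stop("duplicate allele for cell ", cid, ": ",
           paste(keys[duplicated(keys)], collapse = ", "))
    }
    names(dev) <- keys
    meta <- sub[1L, ]
    blank2na <- function(v) if (is.na(v) || v == "") NA_character_ else v
    cells[[cid]] <- cell_signature(
      cell_id = cid, mouse_id = meta$mouse_id,
      age_days = as.integer(meta$age_days), population = meta$population,
      deviations = dev, multiallelic_loci = multi,
      ovary_side = blank2na(meta$ovary_side),
      follicle_id = blank2na(meta$follicle_id),
      plate_id = blank2na(meta$plate_id),
      pcr_repeat_of = blank2na(meta$pcr_repeat_of)
    )
  }
  unname(cells)
}

#' Write a signature table
#'
#' Inverse of [read_signature_table()]: one row per observed allele plus one
#' row per multiallelic locus flag. Reading the written file back yields the
#' same list of signatures.
#'
#' @param cells list of `cell_signature`.
#' @param path output TSV path.
#' @export
write_signature_table <- function(cells, path) {
  rows <- lapply(cells, function(cl) {
    na2blank <- function(v) if (is.na(v)) "" else v
    meta <- data.frame(
      cell_id = cl$cell_id, mouse_id = cl$mouse_id,
      age_days = cl$age_days, population = cl$population,
      ovary_side = na2blank(cl$ovary_side),
      follicle_id = na2blank(cl$follicle_id),
      plate_id = na2blank(cl$plate_id),
      pcr_repeat_of = na2blank(cl$pcr_repeat_of),
      stringsAsFactors = FALSE
    )
    keys <- names(cl$deviations)
    out <- NULL
    if (length(keys)) {
      out <- cbind(meta[rep(1, length(keys)), , drop = FALSE],
                   locus_id = key_locus(keys),
                   parental = sub("^.*\\|", "", keys),
                   deviation = as.integer(cl$deviations),
                   multiallelic_flag = "0")
    }
    if (length(cl$multiallelic_loci)) {
      m <- cbind(meta[rep(1, length(cl$multiallelic_loci)), , drop = FALSE],
                 locus_id = cl$multiallelic_loci,
                 parental = "", deviation = "",
                 multiallelic_flag = "1")
      out <- rbind(out, m)
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- as.data.frame(matrix(character(), ncol = length(.sig_columns),
                                dimnames = list(NULL, .sig_columns)))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality filter: minimum amplified alleles per cell
#'
#' Cells are retained only if strictly more than `min_alleles` alleles
#' amplified (the study kept cells with more than 25 amplified alleles of the
#' 162 possible).
#'
#' @param cells list of `cell_signature`.
#' @param min_alleles strict lower bound (default 25).
#' @return filtered list, original order preserved.
#' @export
filter_min_alleles <- function(cells, min_alleles = 25L) {
  stopifnot(min_alleles >= 0)
  keep <- vapply(cells, function(cl) length(cl$deviations) > min_alleles,
                 logical(1))
  cells[keep]
}

#' Exclude loci that failed a plate negative control
#'
#' Each PCR plate carried a water negative control; a locus showing signal in
#' the control is excluded from every sample run on that plate (both parental
#' alleles removed).
#'
#' @param cells list of `cell_signature`.
#' @param failed data.frame with columns `plate_id`, `locus_id` (or a list of
#'   two-element character vectors).
#' @return the cells with affected alleles removed.
#' @export
apply_plate_negative_control <- function(cells, failed) {
  if (is.list(failed) && !is.data.frame(failed)) {
    failed <- do.call(rbind, lapply(failed, function(p)
      data.frame(plate_id = p[[1]], locus_id = p[[2]],
                 stringsAsFactors = FALSE)))
  }
  if (is.null(failed) || nrow(failed) == 0) return(cells)
  lapply(cells, function(cl) {
    if (is.na(cl$plate_id)) return(cl)
    bad <- failed$locus_id[failed$plate_id == cl$plate_id]
    if (!length(bad)) return(cl)
    keep <- !(key_locus(names(cl$deviations)) %in% bad)
    cl$deviations <- cl$deviations[keep]
    cl
  })
}

#' Root (putative zygote) signature
#'
#' The root pseudo-cell's signature is the per-allele median of the observed
#' deviations across all sampled cells. Deviations are integers, so with an
#' even number of observations one of the two middle values must be chosen:
#' `tie = "zero"` (default) takes the middle value closer to zero deviation,
#' the least-mutated root estimate consistent with the sign convention;
#' `"lower"`/`"upper"` take a fixed side.
#'
#' @param cells list of `cell_signature` (at least one).
#' @param tie even-count tie rule: `"zero"`, `"lower"` or `"upper"`.
#' @return object of class `root_signature` with element `deviations`, a
#'   named integer vector covering every allele observed in at least one cell.
#' @export
compute_root_signature <- function(cells, tie = c("zero", "lower", "upper")) {
  tie <- match.arg(tie)
  if (!length(cells)) stop("compute_root_signature needs >= 1 cell")
  keys <- sort(unique(unlist(lapply(cells, function(cl) names(cl$deviations)))))
  vals <- lapply(cells, `[[`, "deviations")
  med <- vapply(keys, function(k) {
    v <- sort(unname(unlist(lapply(vals, function(d) d[k]))))  # sort drops NA
    n <- length(v)
    if (n %% 2L == 1L) return(v[(n + 1L) %/% 2L])
    lo <- v[n %/% 2L]
    hi <- v[n %/% 2L + 1L]
    switch(tie,
           zero = if (abs(lo) <= abs(hi)) lo else hi,
           lower = lo,
           upper = hi)
  }, integer(1))
  structure(list(deviations = med), class = "root_signature")
}

#' @export
print.root_signature <- function(x, ...) {
  cat(sprintf("<root_signature> %d alleles, %d non-zero\n",
              length(x$deviations), sum(x$deviations != 0)))
  invisible(x)
}

#' Standard QC pipeline
#'
#' Applies the study's filters in their fixed order: plate negative-control
#' locus exclusion, then (multiallelic loci having been excluded at read
#' time) the strict minimum-allele cell filter.
#'
#' @inheritParams filter_min_alleles
#' @inheritParams apply_plate_negative_control
#' @return filtered list of `cell_signature`.
#' @export
qc_filter <- function(cells, failed = NULL, min_alleles = 25L) {
  if (!is.null(failed)) cells <- apply_plate_negative_control(cells, failed)
  filter_min_alleles(cells, min_alleles)
}
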
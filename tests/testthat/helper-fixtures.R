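# Shared fixtures: a tiny 3-locus panel and hand-built cells.

tiny_panel <- function() {
  locus_panel(locus_id = c("L1", "L2", "L3"),
              repeat_unit_len = c(1L, 2L, 2L),
              allele_a_ref_size = c(20L, 25L, 30L),
              allele_b_ref_size = c(32L, 37L, 42L))
}

# a cell with explicit deviations given as list(locus|parental = step)
tiny_cell <- function(id, dev, mouse = "M1", age = 30L, pop = "oocyte",
                      multi = character(), plate = "P1", side = NA) {
  cell_signature(cell_id = id, mouse_id = mouse, age_days = age,
                 population = pop,
                 deviations = unlist(dev),
                 multiallelic_loci = multi, plate_id = plate,
                 ovary_side = side)
}

# write a signature TSV from a data.frame of rows
write_sig_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a full signature-table row
sig_row <- function(cell_id, locus_id, parental, deviation,
                    multiallelic_flag = "0", mouse_id = "M1",
                    age_days = 30L, population = "oocyte",
                    ovary_side = "", follicle_id = "", plate_id = "P1",
                    pcr_repeat_of = "") {
  data.frame(cell_id = cell_id, mouse_id = mouse_id, age_days = age_days,
             population = population, ovary_side = ovary_side,
             follicle_id = follicle_id, plate_id = plate_id,
             pcr_repeat_of = pcr_repeat_of, locus_id = locus_id,
             parental = parental, deviation = deviation,
             multiallelic_flag = multiallelic_flag,
             stringsAsFactors = FALSE)
}

# independent brute-force stepwise pmf: sum over mutation counts m of
# Binom(m; t, mu) times the +/-1 random-walk point mass
bf_step_pmf <- function(delta, t, mu) {
  delta <- abs(delta)
  if (t == 0) return(as.numeric(delta == 0))
  m <- seq.int(delta, t)
  m <- m[(m - delta) %% 2 == 0]
  if (!length(m)) return(0)
  sum(choose(t, m) * mu^m * (1 - mu)^(t - m) *
        choose(m, (m + delta) / 2) / 2^m)
}
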
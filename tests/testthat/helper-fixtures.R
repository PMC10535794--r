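# Shared fixture builders (all data generated in code).

# Minimal valid concentration table: one full cell or an arbitrary set of
# rows given as a data frame of overrides.
make_conc <- function(sector = "lower", matrix = "muscle", element = "Pb",
                      values = c(0.2, 0.24, 0.28)) {
  data.frame(sector = sector, matrix = matrix, element = element,
             replicate_id = seq_along(values), concentration = values,
             stringsAsFactors = FALSE)
}

# A complete paired mini-design: every matrix for the given cells, equal
# replicate counts, deterministic values.
make_paired_design <- function(sectors = c("upper", "lower"),
                               elements = c("As", "Pb"), n = 3) {
  grid <- expand.grid(sector = sectors, matrix = c("muscle", "water",
                                                   "sediment"),
                      element = elements, replicate_id = seq_len(n),
                      stringsAsFactors = FALSE)
  base <- c(muscle = 0.2, water = 0.05, sediment = 20)
  grid$concentration <- base[grid$matrix] *
    (1 + 0.1 * grid$replicate_id) *
    (1 + 0.05 * match(grid$element, elements))
  grid
}
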
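# Small hand-built fixtures used across test files.

# one record of a lineage table, with defaults for brevity
rec <- function(cell_id, parent_id = NA, generation = 1L, birth = 0,
                mitosis = NA, end = 4320, phenotype = NA,
                fate = "ALIVE_AT_END", n_daughters = 0L,
                lineage_id = sub("\\..*$", "", cell_id)) {
  data.frame(lineage_id = lineage_id, cell_id = cell_id,
             parent_id = parent_id, generation = generation,
             birth_time = birth, mitosis_start = mitosis, end_time = end,
             phenotype = phenotype, fate = fate,
             n_daughters = as.integer(n_daughters),
             stringsAsFactors = FALSE)
}

# root dividing at 600 into two daughters alive at movie end
three_cell_table <- function() {
  lineage_table(rbind(
    rec("L1.1", mitosis = 540, end = 600, phenotype = "NO_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L1.1.1", parent_id = "L1.1", generation = 2, birth = 600),
    rec("L1.1.2", parent_id = "L1.1", generation = 2, birth = 600)))
}

# one FUCCI segment row
seg <- function(cell_id, index, phase, start, end, event = NA,
                generation = 1L, parent_id = NA,
                lineage_id = sub("\\..*$", "", cell_id)) {
  data.frame(cell_id = cell_id, lineage_id = lineage_id,
             parent_id = parent_id, generation = generation,
             segment_index = as.integer(index), phase = phase,
             start_min = start, end_min = end, terminal_event = event,
             stringsAsFactors = FALSE)
}
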
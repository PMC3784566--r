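# Packaged study tables, loaded once per test session
table1 <- read_matings(crisprflux_example("table1_matings.tsv"))
# same-plasmid comparison: wild-type plasmid into immune vs permissive hosts
table1_pg0400 <- dplyr::filter(table1, donor_plasmid == "pG0400")
table3 <- read_fluctuation_counts(crisprflux_example("table3_fluctuation.tsv"))
table2 <- read_genotypes(crisprflux_example("table2_genotypes.csv"))

counts_independent <-
  table3$transconjugants[table3$design == "independent_cultures"]
counts_aliquots <- table3$transconjugants[table3$design == "aliquots"]

# power-of-two culture sizes so growth is a whole number of doublings
fluc_n0 <- 2^7
fluc_nf <- 2^20
fluc_gens <- 13
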
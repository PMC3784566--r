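test_that("each notation form parses into the right structured call", {
  spc <- parse_genotype("Δspc1,2")
  expect_identical(spc$category, "spacer_deletion")
  expect_identical(spc$spacers, "1,2")

  ins <- parse_genotype("csm6(617)::IS256-d")
  expect_identical(ins$category, "is_insertion")
  expect_identical(ins$gene, "csm6")
  expect_identical(ins$position, 617L)
  expect_identical(ins$element, "IS256")
  expect_identical(ins$orientation, "direct")
  expect_identical(parse_genotype("csm5(558)::IS256-i")$orientation, "inverted")

  del <- parse_genotype("Δ2387081–2520252 (IS256)")
  expect_identical(del$category, "locus_deletion")
  expect_identical(del$del_start, 2387081L)
  expect_identical(del$del_end, 2520252L)
  expect_identical(del$span, 133172L)
  expect_identical(del$mediator, "IS256")
  # plain hyphen accepted interchangeably with the en dash
  expect_identical(parse_genotype("Δ2387081-2520252 (IS256)")[-1], del[-1])

  fs <- parse_genotype("cas10(ΔA979). Frameshift")
  expect_identical(fs$category, "frameshift")
  expect_identical(fs$gene, "cas10")
  expect_identical(fs$position, 979L)

  sp <- parse_genotype("spc1(ΔA1)")
  expect_identical(sp$category, "spacer_point")

  non <- parse_genotype("cas10(C1411T; Q471Stop)")
  expect_identical(non$category, "nonsense")
  expect_identical(non$nt_change, "C1411T")
  expect_identical(non$aa_change, "Q471Stop")

  mis <- parse_genotype("csm4(G566T; G189V)")
  expect_identical(mis$category, "missense")
})

test_that("unparseable strings raise errors naming the offender", {
  expect_error(parse_genotype("totally wrong"), "totally wrong")
  expect_error(parse_genotype(""), "non-empty")
  expect_error(parse_genotype("Δ500-100 (IS256)"), "start >= end")
  expect_error(parse_genotype(c("Δspc1", NA)), "non-empty")
})

test_that("parse -> serialize -> parse round-trips every fixture genotype", {
  calls <- parse_genotype(table2$genotype_string)
  back <- serialize_genotype(calls)
  reparsed <- parse_genotype(back)
  expect_equal(reparsed[-1], calls[-1]) # all fields except the raw string
})

test_that("fixture spectrum matches the published tallies", {
  tally <- tally_spectrum(table2)
  expect_identical(sum(tally$n), nrow(table2))
  counts <- setNames(tally$n, tally$category)
  expect_identical(counts[["locus_deletion"]], 55L)
  expect_identical(counts[["is_insertion"]], 24L)
  expect_identical(counts[["spacer_deletion"]], 14L)
  expect_identical(counts[["frameshift"]], 13L)
  expect_identical(counts[["nonsense"]], 3L)
  expect_identical(counts[["missense"]], 1L)
  expect_identical(counts[["spacer_point"]], 1L)
  expect_equal(sum(tally$proportion), 1)
})

test_that("empty record lists tally to zero", {
  tally <- tally_spectrum(table2[0, ])
  expect_true(all(tally$n == 0L))
  expect_identical(nrow(tally), 7L)
})

test_that("deletion spans and variants match the published summary", {
  spans <- deletion_spans(table2)
  s <- summarize_spans(spans)
  expect_identical(s$n_deletions, 55L)
  expect_identical(s$n_variants, 16L)
  expect_identical(s$min_span, 65712L)
  expect_identical(s$max_span, 306488L)
  # the smallest deletion is the shared R14/R51 variant; the largest is B39's
  expect_true(all(
    spans$del_start[spans$span == 65712] == 2515497
  ))
  expect_identical(spans$isolate_id[spans$span == 306488], "B39")
})

test_that("every fixture IS insertion hits csm5, csm6 or cas6", {
  calls <- parse_genotype(table2$genotype_string)
  ins <- calls[calls$category == "is_insertion", ]
  expect_true(all(ins$gene %in% c("csm5", "csm6", "cas6")))
  expect_true(all(ins$element == "IS256"))
})

test_that("genome fractions reproduce the published percentages", {
  expect_equal(genome_fraction(65712), 2.5, tolerance = 0.2 / 2.5)
  frac_max <- genome_fraction(306488)
  expect_gte(frac_max, 11.5)
  expect_lte(frac_max, 11.9)
  # the chromosome+plasmid convention lands on the printed 11.6
  expect_equal(genome_fraction(306488, 2.643e6), 11.6, tolerance = 0.01)
  expect_identical(genome_fraction(100, 100), 100)
  expect_error(genome_fraction(200, 100), "exceed")
  expect_error(genome_fraction(0), "> 0")
})
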
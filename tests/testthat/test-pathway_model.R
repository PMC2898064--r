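test_that("reaction FI extraction enumerates non-output participants", {
  r <- reaction_record("r1", inputs = c("A", "B"), catalysts = "C",
                       inhibitors = "D", outputs = "E")
  fis <- extract_fis_from_reaction(r)
  keys <- sort(pair_keys(fis$protein_a, fis$protein_b))
  expect_equal(keys, c("A B", "A C", "A D", "B C", "B D", "C D"))
  expect_false("E" %in% c(fis$protein_a, fis$protein_b))

  # single participant and output-only proteins give no pairs
  expect_equal(nrow(extract_fis_from_reaction(reaction_record("r2", inputs = "A"))), 0L)
  expect_equal(nrow(extract_fis_from_reaction(
    reaction_record("r3", inputs = "A", outputs = c("A", "B")))), 0L)
})

test_that("direction tags follow regulator-to-input semantics", {
  r <- reaction_record("r1", inputs = c("A", "B"), catalysts = "C",
                       inhibitors = "D")
  fis <- extract_fis_from_reaction(r)
  rownames(fis) <- pair_keys(fis$protein_a, fis$protein_b)
  expect_equal(fis["A C", "direction"], "activates")
  expect_equal(fis["A C", "source_protein"], "C")
  expect_equal(fis["A D", "direction"], "inhibits")
  expect_equal(fis["A D", "source_protein"], "D")
  expect_equal(fis["A B", "direction"], "undirected")  # input-input
  expect_equal(fis["C D", "direction"], "undirected")  # regulator-regulator
})

test_that("complex FI extraction flattens recursively", {
  expect_equal(sort(with(extract_fis_from_complex(
    complex_record("c1", c("A", "B", "C"))),
    pair_keys(protein_a, protein_b))), c("A B", "A C", "B C"))
  expect_equal(nrow(extract_fis_from_complex(complex_record("c2", "A"))), 0L)

  reg <- list(sub = complex_record("sub", c("B", "C")))
  nested <- complex_record("c3", c("A", "complex:sub"))
  expect_equal(sort(with(extract_fis_from_complex(nested, reg),
                         pair_keys(protein_a, protein_b))),
               c("A B", "A C", "B C"))
  expect_warning(extract_fis_from_complex(complex_record("c4", character(0))),
                 "no protein components")
})

test_that("cyclic complex nesting is a structural error", {
  reg <- list(x = complex_record("x", c("A", "complex:y")),
              y = complex_record("y", c("B", "complex:x")))
  expect_error(flatten_members("complex:x", reg), "cyclic")
})

test_that("splice isoforms collapse to base accessions", {
  r <- reaction_record("r", inputs = c("P12345-1", "P12345-2"),
                       catalysts = "Q00001")
  fis <- extract_fis_from_reaction(r)
  expect_equal(sort(pair_keys(fis$protein_a, fis$protein_b)),
               "P12345 Q00001")
})

test_that("extraction matches brute-force enumeration on random reactions", {
  set.seed(11)
  prots <- sprintf("X%02d", 1:12)
  for (i in 1:25) {
    inputs <- sample(prots, sample(0:3, 1))
    cats <- sample(prots, sample(0:2, 1))
    acts <- sample(prots, sample(0:1, 1))
    inhs <- sample(prots, sample(0:1, 1))
    outs <- sample(prots, sample(0:2, 1))
    fis <- extract_fis_from_reaction(
      reaction_record("r", inputs, cats, acts, inhs, outs))
    expect_setequal(pair_keys(fis$protein_a, fis$protein_b),
                    oracle_reaction_pairs(inputs, cats, acts, inhs))
    n <- length(unique(c(inputs, cats, acts, inhs)))
    expect_equal(nrow(fis), choose(n, 2))
    expect_true(all(fis$protein_a != fis$protein_b))
  }
})

test_that("pathway FI sets deduplicate and merge direction over sources", {
  p1 <- pathway_record("pw1", source = "dbA",
                       reactions = list(reaction_record("r", inputs = c("A", "B"))))
  p2 <- pathway_record("pw2", source = "dbB",
                       complexes = list(complex_record("c", c("A", "B"))))
  fis <- build_pathway_fi_set(list(p1, p2))
  expect_equal(nrow(fis), 1L)
  expect_equal(fis$sources, "dbA;dbB")

  # catalysis direction survives a merge with an undirected complex pair
  p3 <- pathway_record("pw3", source = "dbC",
                       reactions = list(reaction_record("r", inputs = "B",
                                                        catalysts = "A")),
                       complexes = list(complex_record("c", c("A", "B"))))
  fis3 <- build_pathway_fi_set(list(p3))
  expect_equal(nrow(fis3), 1L)
  expect_equal(fis3$direction, "activates")
  expect_equal(fis3$source_protein, "A")

  expect_equal(nrow(build_pathway_fi_set(list())), 0L)
})

test_that("regulation records yield oriented expression FIs", {
  pw <- pathway_record("pw", source = "tred",
                       regulations = list(list(id = "g1", factor = "TF1",
                                               targets = c("A", "B"))))
  fis <- build_pathway_fi_set(list(pw))
  expect_equal(nrow(fis), 2L)
  expect_true(all(fis$direction == "expression_regulates"))
  expect_true(all(fis$source_protein == "TF1"))
})

test_that("extraction is idempotent and order-independent", {
  pw <- small_world()$pathways
  a <- build_pathway_fi_set(pw)
  b <- build_pathway_fi_set(rev(pw))
  expect_equal(a, b)
  expect_equal(dedup_fi_table(a), a)
})

test_that("pathway TSV round-trips through read and write", {
  pw <- small_world()$pathways
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_tsv(pw, f)
  back <- read_pathway_tsv(f)
  expect_equal(build_pathway_fi_set(back), build_pathway_fi_set(pw))
  expect_error(read_pathway_tsv(
    withr::local_tempfile(lines = "REACTION\tr1\tbogus=A")), "malformed|unknown")
})

test_that("FI tables round-trip through TSV", {
  fis <- small_world()$reference_fis
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fi_tsv(fis, f)
  expect_equal(read_fi_tsv(f), fis)
})
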
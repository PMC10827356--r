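test_that("every documented fixture verdict is reproduced", {
  corp <- paper_corpus()
  cls <- pfas_classify(corp, smiles = "smiles", id = "name")
  exp <- corpus_expectations()
  expect_gte(nrow(exp), 50L)
  chk <- dplyr::left_join(exp, cls,
                          by = c(name = "record_id", "definition_id"))
  expect_false(any(is.na(chk$is_pfas)))
  for (i in seq_len(nrow(chk))) {
    expect_identical(chk$is_pfas[i], chk$expected[i],
                     label = paste(chk$name[i], chk$definition_id[i]))
  }
})

test_that("documented percentages are reproduced to printed precision", {
  corp <- paper_corpus()
  cls <- pfas_classify(corp, smiles = "smiles", id = "name",
                       definitions = "pfasstruct_v5")
  m <- dplyr::left_join(corp, cls, by = c(name = "record_id"))
  # printed integers are rounded or truncated: match within one percent point
  excl <- dplyr::filter(m, !is.na(exp_pct_f_excl_h))
  expect_gt(nrow(excl), 0L)
  expect_true(all(abs(100 * excl$atom_fraction_excl_h - excl$exp_pct_f_excl_h) < 1))
  all_at <- dplyr::filter(m, !is.na(exp_pct_f_all_atoms))
  expect_true(all(abs(100 * all_at$atom_fraction_incl_h - all_at$exp_pct_f_all_atoms) < 1))
  mass <- dplyr::filter(m, !is.na(exp_mass_pct))
  expect_true(all(abs(100 * mass$mass_fraction - mass$exp_mass_pct) < 1))
  # the one value printed to a decimal place matches to that place
  ftoh <- dplyr::filter(m, name == "6:2 fluorotelomer alcohol")
  expect_equal(round(100 * ftoh$mass_fraction, 1), 67.8)
})

test_that("the shipped corpus CSV matches paper_corpus()", {
  path <- system.file("extdata", "paper_corpus.csv", package = "pfasdef")
  expect_true(nzchar(path))
  shipped <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(shipped), names(paper_corpus()))
  expect_identical(shipped$smiles, paper_corpus()$smiles)
  expect_equal(as.data.frame(shipped), as.data.frame(paper_corpus()))
})

test_that("the generator is deterministic and leaves the RNG alone", {
  a <- generate_fluorochemicals(50, seed = 123)
  b <- generate_fluorochemicals(50, seed = 123)
  expect_identical(a, b)
  c <- generate_fluorochemicals(50, seed = 124)
  expect_false(identical(a$smiles, c$smiles))

  set.seed(99)
  before <- .Random.seed
  invisible(generate_fluorochemicals(5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("construction-time metadata agrees with the formula pipeline", {
  gen <- generate_fluorochemicals(200, seed = 5)
  expect_identical(nrow(gen), 200L)
  recs <- parse_structures(gen$smiles, gen$id)
  statuses <- vapply(recs, `[[`, character(1), "status")
  expect_true(all(statuses == "ok"))
  for (i in seq_len(nrow(gen))) {
    f <- recs[[i]]$formula
    counts <- unclass(f)
    n_h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
    expect_identical(pfasdef:::formula_count(f, "F"), gen$meta_n_f[i],
                     label = gen$smiles[i])
    expect_identical(sum(counts) - n_h, gen$meta_n_heavy[i],
                     label = gen$smiles[i])
    expect_identical(n_h, gen$meta_n_h[i], label = gen$smiles[i])
    expect_equal(100 * fluorine_atom_fraction(f), gen$meta_pct_f_excl_h[i],
                 label = gen$smiles[i])
  }
})

test_that("generator knobs shape the output as documented", {
  pf <- generate_fluorochemicals(60, seed = 2,
                                 params = synthesis_params(perfluorinate = TRUE))
  expect_true(all(pf$meta_n_h == 0L))
  expect_false(any(grepl("aromatic", pf$scaffold)))  # aromatic disabled
  # every perfluorinated molecule contains a fully fluorinated carbon
  recs <- parse_structures(pf$smiles, pf$id)
  expect_true(all(vapply(recs, oracle_has_ffc, logical(1))))

  none <- generate_fluorochemicals(60, seed = 2,
                                   params = synthesis_params(p_f = 0, p_cl = 0,
                                                             p_br = 0))
  expect_true(all(none$meta_n_f == 0L))

  mix <- generate_fluorochemicals(300, seed = 3,
                                  params = synthesis_params(p_second_component = 1))
  expect_true(all(mix$n_components == 2L))
  expect_error(synthesis_params(p_f = 1.2))
  expect_error(generate_fluorochemicals(0, seed = 1))
})

test_that("generate_formulas yields parseable deterministic formulas", {
  f1 <- generate_formulas(100, seed = 9)
  f2 <- generate_formulas(100, seed = 9)
  expect_identical(f1, f2)
  parsed <- lapply(f1, parse_formula)
  expect_length(parsed, 100L)
  expect_true(all(vapply(parsed, inherits, logical(1), "mol_formula")))
})
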
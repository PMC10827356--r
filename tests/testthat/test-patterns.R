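test_that("pattern_spec applies kind defaults and validates parameters", {
  p <- pattern_spec("x", "cf2_pair")
  expect_identical(p$params$min_f_a, 2L)
  expect_identical(p$params$min_f_b, 1L)
  expect_false(p$params$allow_h_a)
  expect_error(pattern_spec("x", "no_such_kind"))
  expect_error(pattern_spec("x", "cf2_pair", min_run = 3), "unknown parameter")
  q <- pattern_spec("q", "cf2_hetero_cf2", hetero = c("O", "S"))
  expect_identical(q$params$hetero, c("O", "S"))
})

test_that("cf2_pair matching finds unordered unique embeddings", {
  rec <- parse_structure("FC(F)(F)C(F)(F)F", "C2F6")
  m <- match_pattern(rec, pattern_spec("p", "cf2_pair", min_f_b = 2L))
  expect_length(m, 1L)   # the symmetric pair counts once

  pfba <- parse_structure("OC(=O)C(F)(F)C(F)(F)C(F)(F)F", "PFBA")
  m2 <- match_pattern(pfba, pattern_spec("p", "cf2_pair", min_f_b = 2L))
  expect_length(m2, 2L)  # CF3-CF2 and CF2-CF2

  # hydrogen on an attachment position blocks the default (no-H) variant
  htfe <- parse_structure("FC(F)C(F)F", "CHF2CHF2")
  expect_length(match_pattern(htfe, pattern_spec("p", "cf2_pair", min_f_b = 2L)), 0L)
  expect_length(match_pattern(htfe, pattern_spec(
    "p", "cf2_pair", min_f_b = 2L, allow_h_a = TRUE, allow_h_b = TRUE)), 1L)

  # require_h demands at least one hydrogen on that carbon
  hfc134a <- parse_structure("FCC(F)(F)F", "HFC-134a")
  s5 <- pattern_spec("s5", "cf2_pair", allow_h_b = TRUE, require_h_b = TRUE)
  expect_length(match_pattern(hfc134a, s5), 1L)
  expect_length(match_pattern(rec, s5), 0L)  # C2F6 has no H anywhere
})

test_that("perfluoroalkyl_run and hetero/bis-CF3 kinds match their units", {
  pfba <- parse_structure("OC(=O)C(F)(F)C(F)(F)C(F)(F)F", "PFBA")
  runs <- match_pattern(pfba, pattern_spec("r", "perfluoroalkyl_run"))
  expect_length(runs, 1L)
  expect_length(runs[[1]], 3L)
  c2f6 <- parse_structure("FC(F)(F)C(F)(F)F", "C2F6")
  expect_length(match_pattern(c2f6, pattern_spec("r", "perfluoroalkyl_run")), 0L)

  ether <- parse_structure("FC(F)(F)OC(F)(F)F", "CF3OCF3")
  hits <- match_pattern(ether, pattern_spec("e", "cf2_hetero_cf2"))
  expect_length(hits, 1L)
  expect_length(hits[[1]], 3L)
  # sulfur bridge only matches when S is in the hetero set
  thio <- parse_structure("FC(F)(F)SC(F)(F)F", "CF3SCF3")
  expect_length(match_pattern(thio, pattern_spec("e", "cf2_hetero_cf2")), 0L)
  expect_length(match_pattern(thio, pattern_spec(
    "e", "cf2_hetero_cf2", hetero = c("O", "S"))), 1L)

  bis <- parse_structure("CC(C(F)(F)F)C(F)(F)F", "branched")
  expect_length(match_pattern(bis, pattern_spec("b", "bis_cf3")), 0L)
  expect_length(match_pattern(bis, pattern_spec(
    "b", "bis_cf3", allow_h_central = TRUE)), 1L)
  quart <- parse_structure("FC(F)(F)C(C)(C)C(F)(F)F", "quaternary")
  expect_length(match_pattern(quart, pattern_spec("b", "bis_cf3")), 1L)
})

test_that("pattern matches are deterministic and sorted", {
  rec <- parse_structure("FC(F)(F)C(F)(F)C(F)(F)F", "C3F8")
  p <- pattern_spec("p", "cf2_pair", min_f_b = 2L)
  m1 <- match_pattern(rec, p)
  m2 <- match_pattern(rec, p)
  expect_identical(m1, m2)
  keys <- vapply(m1, function(x) paste(x, collapse = ","), character(1))
  expect_identical(keys, sort(keys))
  expect_true(all(vapply(m1, function(x) !is.unsorted(x), logical(1))))
})

test_that("embeddings never span disconnected components", {
  rec <- parse_structure("FC(F)(F)F.FC(F)(F)F", "two CF4")
  expect_length(match_pattern(rec, pattern_spec("p", "cf2_pair")), 0L)
  ether <- parse_structure("FC(F)(F)F.OC(F)(F)F", "no bridge")
  expect_length(match_pattern(ether, pattern_spec("e", "cf2_hetero_cf2")), 0L)
})

test_that("native matcher agrees with the OpenBabel SMARTS oracle", {
  library(ChemmineR)
  # single-component, multi-atom structures (OpenBabel cannot represent
  # single-atom or multi-fragment records faithfully enough for this check)
  corp <- probe_corpus()
  corp <- corp[!grepl(".", corp$smiles, fixed = TRUE) & corp$name != "methane", ]
  gen <- generate_fluorochemicals(120, seed = 7)
  smiles <- c(corp$smiles, gen$smiles[gen$n_components == 1L])
  names(smiles) <- c(corp$name, gen$id[gen$n_components == 1L])

  recs <- parse_structures(smiles)
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  valid <- ChemmineR::validSDF(sdfs)
  expect_gt(sum(valid), 100L)
  recs <- recs[valid]
  sdfs <- sdfs[valid]

  pats <- list()
  for (d in builtin_definitions()) {
    for (p in d$patterns) if (!is.null(p$smarts)) pats[[p$id]] <- p
  }
  expect_gte(length(pats), 8L)
  for (p in pats) {
    native <- vapply(recs, function(r) length(match_pattern(r, p)) > 0L,
                     logical(1))
    ob <- as.numeric(ChemmineR::smartsSearchOB(
      sdfs, p$smarts, uniqueMatches = TRUE)) > 0
    expect_identical(unname(native), unname(ob), label = p$id)
  }
})
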
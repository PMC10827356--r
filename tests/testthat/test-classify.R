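test_that("classify returns verdict plus full evidence", {
  rec <- parse_structure("FC(F)=C(F)F", "TFE")
  res <- classify(rec, "pfasstruct_v5")
  expect_s3_class(res, "classification_result")
  expect_true(res$is_pfas)
  expect_setequal(unique(res$evidence$kind), c("filter", "formula", "pattern"))
  # the formula clause carries the verdict: no substructure matches TFE
  expect_false(any(res$evidence$passed[res$evidence$kind == "pattern"]))
  expect_true(res$evidence$passed[res$evidence$id == "fluorine_fraction"])
  expect_equal(res$evidence$value[res$evidence$id == "fluorine_fraction"], 4 / 6)

  expect_false(classify(rec, "oecd2021")$is_pfas)
  expect_output(print(res), "PFAS")
})

test_that("exclusion filters veto otherwise-positive records", {
  # perfluoroethyl radical: 100% fluorine but a free radical
  rad <- parse_structure("[C](F)(F)C(F)(F)F", "radical")
  res <- classify(rad, "pfasstruct_v5")
  expect_false(res$is_pfas)
  expect_false(res$evidence$passed[res$evidence$id == "no_radical"])
  # its pattern/formula clauses do fire; only the filter vetoes
  expect_true(any(res$evidence$passed[res$evidence$kind != "filter"]))

  # fluoride salt: fully fluorinated by atom count but no C-F bond
  naf <- classify(parse_structure("[Na+].[F-]", "NaF"), "pfasstruct_v5")
  expect_false(naf$is_pfas)
  expect_false(naf$evidence$passed[naf$evidence$id == "require_cf_bond"])

  # trifluoroacetate anion: net charge defeats the v1 charged-species rule
  tfa_anion <- parse_structure("[O-]C(=O)C(F)(F)C(F)(F)C(F)(F)F", "PFBA anion")
  res_v1 <- classify(tfa_anion, "pfasstruct_v1")
  expect_false(res_v1$is_pfas)
  expect_false(res_v1$evidence$passed[res_v1$evidence$id == "no_charged"])
})

test_that("multicomponent formula policy differs only in the formula clause", {
  # unsaturated fluoromonomer shipped with a long alkane diluent: the fragment
  # is 67% fluorine but the whole record only 25%
  mix <- parse_structure("FC(F)=C(F)F.CCCCCCCCCC", "mixture")
  expect_true(classify(mix, "pfasstruct_v5", policy = "per_component")$is_pfas)
  expect_false(classify(mix, "pfasstruct_v5", policy = "whole_record")$is_pfas)
  # substructure matching is per-component under both policies
  salt <- parse_structure("[Na+].[O-]C(=O)C(F)(F)C(F)(F)C(F)(F)F", "Na-PFBA")
  expect_true(classify(salt, "tsca2021", policy = "whole_record")$is_pfas)
})

test_that("pfas_classify returns a tidy row per record x definition", {
  out <- pfas_classify(c(PFBA = "OC(=O)C(F)(F)C(F)(F)C(F)(F)F", methane = "C"),
                       definitions = c("oecd2021", "pfasstruct_v5"))
  expect_s3_class(out, "tbl_df")
  expect_identical(nrow(out), 4L)
  expect_true(all(c("record_id", "definition_id", "is_pfas", "evidence",
                    "formula", "f_count", "atom_fraction_excl_h",
                    "atom_fraction_incl_h", "mass_fraction", "f_to_c_ratio")
                  %in% names(out)))
  expect_true(all(vapply(out$evidence, is.data.frame, logical(1))))
  expect_identical(out$is_pfas,
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("parse failures are skipped with a report, never fatal", {
  expect_message(
    out <- pfas_classify(c(ok = "CF", broken = "C1CC"),
                         definitions = "pfasstruct_v5"),
    "skipped"
  )
  expect_identical(unique(out$record_id), "ok")
  sk <- attr(out, "skipped")
  expect_identical(sk$record_id, "broken")
  expect_match(sk$message, "ring")
})

test_that("classification is deterministic", {
  corp <- paper_corpus()
  a <- pfas_classify(corp, smiles = "smiles", id = "name")
  b <- pfas_classify(corp, smiles = "smiles", id = "name")
  expect_identical(a, b)
})

test_that("a perfluoroalkyl run of three carbons entails the 2021 unit", {
  # every carbon of a -CnF2n- run is itself a fully fluorinated methyl or
  # methylene, so run >= 3 must imply an oecd2021-positive verdict. (The 2018
  # ether clause does NOT entail it: CClF2-O-CClF2 has no fully fluorinated
  # carbon, which the codified patterns reproduce.)
  gen <- generate_fluorochemicals(250, seed = 11)
  recs <- pfasdef:::as_record_list(gen)
  runs <- vapply(recs, max_perfluoromethylene_run, integer(1))
  out <- classify_all(recs, definitions = c("oecd2018", "oecd2021"))
  expect_true(all(!(runs >= 3L) | out$matrix$oecd2021))

  ether <- classify(parse_structure("ClC(F)(F)OC(F)(F)Cl", "CClF2-O-CClF2"),
                    "oecd2018")
  expect_true(ether$is_pfas)
  expect_false(classify(parse_structure("ClC(F)(F)OC(F)(F)Cl"), "oecd2021")$is_pfas)
})

test_that("classify_all builds the comparison matrix with totals", {
  m <- classify_all(c(CF4 = "FC(F)(F)F", methane = "C", TFE = "FC(F)=C(F)F"),
                    definitions = c("oecd2021", "pfasstruct_v5"))
  expect_s3_class(m, "pfas_matrix")
  expect_identical(m$matrix$record_id, c("CF4", "methane", "TFE"))
  expect_identical(m$totals, c(oecd2021 = 1L, pfasstruct_v5 = 2L))
  expect_output(print(m), "records x")

  long <- tidy(m)
  expect_identical(nrow(long), 6L)
  g <- glance(m)
  expect_identical(g$n_records, 3L)
  expect_identical(g$n_pfasstruct_v5, 2L)

  plt <- ggplot2::autoplot(m)
  expect_s3_class(plt, "ggplot")
  h <- plot_fluorine_distribution(m$classified)
  expect_s3_class(h, "ggplot")
})
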
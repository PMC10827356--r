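test_that("pattern_overlap flags exactly the redundant v4 substructure", {
  # On a corpus where every pattern can speak for itself, the only extraneous
  # substructure is the perfluoroethyl unit S2: it is a record-level subset of
  # both S1 and S3 by construction.
  pc <- probe_corpus()
  ov <- pattern_overlap(stats::setNames(pc$smiles, pc$name), "pfasstruct_v4")
  expect_s3_class(ov, "overlap_report")
  expect_identical(attr(ov, "definition_id"), "pfasstruct_v4")
  expect_identical(ov$pattern_id[ov$extraneous], "s2_perfluoroethyl")
  expect_identical(ov$unique_hits[ov$pattern_id == "s2_perfluoroethyl"], 0L)
  expect_true(all(ov$unique_hits > 0L | ov$extraneous))
  # report invariants: unique_hits <= total_hits <= corpus size
  expect_true(all(ov$unique_hits <= ov$total_hits))
  expect_true(all(ov$total_hits <= attr(ov, "corpus_size")))
  expect_identical(ov$extraneous, ov$unique_hits == 0L)
  # every S2 hit is also an S1 and an S3 hit
  hits <- attr(ov, "hit_records")
  expect_true(all(hits$s2_perfluoroethyl %in% hits$s1_adjacent_cf2))
  expect_true(all(hits$s2_perfluoroethyl %in% hits$cf2_cf_unit))
  expect_gt(ov$total_hits[ov$pattern_id == "s2_perfluoroethyl"], 0L)
})

test_that("removing an extraneous pattern changes no verdict", {
  pc <- probe_corpus()
  corpus <- stats::setNames(pc$smiles, pc$name)
  v4 <- builtin_definitions()$pfasstruct_v4
  ov <- pattern_overlap(corpus, v4)
  drop <- ov$pattern_id[ov$extraneous]
  pruned <- definition_spec(
    id = "pfasstruct_v4_pruned", label = "v4 without extraneous patterns",
    patterns = unname(v4$patterns[setdiff(names(v4$patterns), drop)]),
    formula_rule = v4$formula_rule, filters = v4$filters,
    filter_params = v4$filter_params
  )
  full <- pfas_classify(corpus, definitions = v4)
  less <- pfas_classify(corpus, definitions = pruned)
  expect_identical(full$is_pfas, less$is_pfas)
  expect_identical(full$record_id, less$record_id)
})

test_that("definition_diff partitions the positive records", {
  corp <- paper_corpus()
  m <- classify_all(corp, smiles = "smiles", id = "name",
                    definitions = c("oecd2021", "pfasstruct_v5"))
  d <- definition_diff(m, "pfasstruct_v5", "oecd2021")
  # disjoint and jointly exhaustive over the positives
  expect_length(intersect(d$only_a, d$only_b), 0L)
  expect_length(intersect(d$only_a, d$both), 0L)
  pos_a <- m$matrix$record_id[m$matrix$pfasstruct_v5]
  pos_b <- m$matrix$record_id[m$matrix$oecd2021]
  expect_setequal(c(d$only_a, d$both), pos_a)
  expect_setequal(c(d$only_b, d$both), pos_b)
  # the unsaturated monomer is combined-definition-only
  expect_true("tetrafluoroethene" %in% d$only_a)
  # the isolated CF2 compound is the reverse split
  expect_true("4,4-difluoroheptane" %in% d$only_b)
  expect_error(definition_diff(m, "pfasstruct_v5", "nope"), "not in matrix")

  # identity: a definition differs from itself nowhere
  same <- definition_diff(m, "oecd2021", "oecd2021")
  expect_length(same$only_a, 0L)
  expect_length(same$only_b, 0L)
  expect_setequal(same$both, pos_b)

  # empty corpus: all three sets empty
  m0 <- classify_all(character(0), definitions = c("oecd2021", "pfasstruct_v5"))
  d0 <- definition_diff(m0, "oecd2021", "pfasstruct_v5")
  expect_true(all(lengths(d0) == 0L))
})

test_that("gap_candidates narrows to fluorinated records the base misses", {
  corp <- paper_corpus()
  ids <- gap_candidates(stats::setNames(corp$smiles, corp$name),
                        "pfasstruct_v4")
  # v5-motivating discovery: highly fluorinated, non-trivial, v4-negative
  expect_true("tetrakis(trifluoromethoxy)methane" %in% ids)
  # trivially fluorinated records are set aside — including the diol, whose
  # six fluorines sit on two CF3 groups with no shared carbon
  expect_false("1,1,1-trifluoroethane" %in% ids)
  expect_false("1,1,1,4,4,4-hexafluorobutane" %in% ids)
  expect_false("1,1,1,4,4,4-hexafluoro-2,3-diphenylbutane-2,3-diol" %in% ids)
  # ...but the branched bis-CF3 compound is retained by the triviality rule
  # and then removed because v4 already captures it
  expect_false("2-(trifluoromethyl)-1,1,1-trifluoropropane" %in% ids)
  # base-positive records are excluded
  expect_false("perfluorobutanoic acid" %in% ids)
  # records below the fluorine floor are excluded
  expect_false("difluoromethane" %in% ids)

  # every candidate is base-negative, non-trivial, and >= min_f fluorines
  recs <- parse_structures(corp$smiles, corp$name)
  for (id in ids) {
    rec <- recs[[id]]
    expect_gte(pfasdef:::formula_count(rec$formula, "F"), 3L)
    expect_false(is_trivially_fluorinated(rec))
    expect_false(classify(rec, "pfasstruct_v4")$is_pfas)
  }
})
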
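test_that("builtin_definitions ships the seven codified definitions", {
  defs <- builtin_definitions()
  expect_named(defs, c("oecd2021", "oecd2018", "tsca2021", "pfasstruct_v1",
                       "pfasstruct_v4", "ccl5", "pfasstruct_v5"))
  v <- validate_registry(defs)
  expect_true(all(v$problems == ""))
  # structural spot checks on the encodings
  expect_length(defs$pfasstruct_v4$patterns, 6L)
  expect_length(defs$pfasstruct_v5$patterns, 4L)
  expect_length(defs$ccl5$patterns, 3L)
  expect_equal(defs$pfasstruct_v5$formula_rule$threshold, 0.30)
  expect_false(defs$pfasstruct_v5$formula_rule$include_h)
  expect_setequal(defs$pfasstruct_v5$filters, c("no_radical", "require_cf_bond"))
  expect_identical(defs$pfasstruct_v1$filter_params$f_count_range, c(4L, 1000L))
  expect_identical(
    defs$pfasstruct_v5$patterns$s4_cf2_q_cf2$params$hetero,
    c("B", "O", "N", "P", "S", "Si")
  )
})

test_that("definition_spec validates its contract", {
  expect_error(definition_spec("empty"), "at least one pattern or a formula")
  p <- pattern_spec("p", "cf2_pair")
  expect_error(definition_spec("dup", patterns = list(p, p)),
               "duplicate pattern id")
  expect_error(definition_spec("f", patterns = list(p), filters = "no_such"),
               "unknown filter")
  expect_error(definition_spec("f", patterns = list(p),
                               filters = "f_count_range"),
               "f_count_range")
  expect_error(definition_spec("f", patterns = list(p),
                               formula_rule = list(threshold = 1.5,
                                                   include_h = FALSE)))
})

test_that("definitions resolve from ids or spec objects, rejecting duplicates", {
  defs <- pfasdef:::as_definition_list(c("oecd2021", "pfasstruct_v5"))
  expect_named(defs, c("oecd2021", "pfasstruct_v5"))
  expect_error(pfasdef:::as_definition_list("nope"), "unknown definition id")
  expect_error(pfasdef:::as_definition_list(c("oecd2021", "oecd2021")),
               "duplicate definition id")
})

test_that("load_registry merges a YAML config over the built-ins", {
  cfg <- system.file("extdata", "example_registry.yaml", package = "pfasdef")
  expect_true(nzchar(cfg))
  reg <- load_registry(cfg)
  # new definition appended
  expect_true("v5_strict" %in% names(reg))
  expect_equal(reg$v5_strict$formula_rule$threshold, 0.5)
  expect_length(reg$v5_strict$patterns, 4L)
  expect_identical(reg$v5_strict$patterns$cf2_q_cf2$params$hetero,
                   c("B", "O", "N", "P", "S", "Si"))
  # built-in overridden by id
  expect_identical(reg$pfasstruct_v1$filter_params$f_count_range, c(4L, 100L))
  # untouched built-ins unchanged
  expect_identical(reg$oecd2021$label, builtin_definitions()$oecd2021$label)

  # the override behaves: >100 fluorines now fails the v1 gate
  big <- paste0("FC(F)(F)", strrep("C(F)(F)", 60), "F")
  expect_false(classify(parse_structure(big), reg$pfasstruct_v1)$is_pfas)
  expect_true(classify(parse_structure(big),
                       builtin_definitions()$pfasstruct_v1)$is_pfas)
})

test_that("load_registry accepts JSON, lists, and rejects bad configs", {
  cfg <- list(definitions = list(list(
    id = "tiny", patterns = list(list(id = "p", kind = "cf2_pair"))
  )))
  reg <- load_registry(cfg)
  expect_true("tiny" %in% names(reg))

  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jf, auto_unbox = TRUE)
  expect_true("tiny" %in% names(load_registry(jf)))

  yf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("definitions:", "  - label: no id here"), yf)
  expect_error(load_registry(yf), "without an 'id'")

  dup <- list(definitions = list(
    list(id = "d", patterns = list(list(id = "p", kind = "cf2_pair"))),
    list(id = "d", patterns = list(list(id = "p", kind = "cf2_pair")))
  ))
  expect_error(load_registry(dup), "duplicate definition id")
  expect_error(load_registry("/no/such/file.yaml"), "not found")

  bad_kind <- list(definitions = list(list(
    id = "b", patterns = list(list(id = "p", kind = "hexagon"))
  )))
  expect_error(load_registry(bad_kind))

  # unquoted YAML element symbols (N, B) degrade to booleans: caught loudly
  trap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("definitions:",
               "  - id: trap",
               "    patterns:",
               "      - {id: q, kind: cf2_hetero_cf2, hetero: [O, N]}"), trap)
  expect_error(load_registry(trap), "non-element value")

  # an empty config leaves the built-ins untouched
  expect_identical(names(load_registry(list())), names(builtin_definitions()))
})
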
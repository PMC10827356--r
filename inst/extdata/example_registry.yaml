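# Example definition-registry config for load_registry().
#
# Blocks whose id matches a built-in definition replace it; new ids are
# appended. Pattern kinds and their parameters are documented in
# ?pattern_spec; filters in ?definition_spec.
definitions:
  # A stricter variant of the combined definition: same four substructures,
  # but the fluorine-fraction clause thresholded at 50% instead of 30%.
  - id: v5_strict
    label: combined definition with a 50% fluorine-fraction clause
    patterns:
      - {id: cf2_cf_unit, kind: cf2_pair, min_f_a: 2, min_f_b: 1}
      - {id: adjacent_cf2, kind: cf2_pair, min_f_a: 2, min_f_b: 2}
      - {id: bis_cf3, kind: bis_cf3}
      - id: cf2_q_cf2
        kind: cf2_hetero_cf2
        # element symbols must be quoted: bare N/B read as YAML booleans
        hetero: ["B", "O", "N", "P", "S", "Si"]
    formula_rule: {threshold: 0.50, include_h: false}
    filters: [no_radical, require_cf_bond]
  # Override of the built-in v1 entry: same substructure, narrower
  # fluorine-count gate (demonstrates replacing a built-in by id).
  - id: pfasstruct_v1
    label: v1 variant with a 4-100 fluorine-count gate
    patterns:
      - id: adjacent_cf2_groups
        kind: cf2_pair
        min_f_a: 2
        min_f_b: 2
        allow_h_a: true
        allow_h_b: true
    filters: [f_count_range, f_to_c_min, no_charged, no_radical, no_isotope]
    filter_params:
      f_count_range: [4, 100]
      f_to_c_min: 0.5
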
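# Example rule file: the reciprocal threshold family of friendship
# definitions and two competing binge-drinker cut-offs on AUDIT-C,
# each bundled (via `set`) with the network-conditioned labels.
tie_rules:
  - name: any_contact
    reciprocity: true
    min_each_weight: 2
  - name: some_contact
    reciprocity: true
    min_each_weight: 3
  - name: strong_friendship
    reciprocity: true
    min_each_weight: 4
  - name: best_friends
    reciprocity: true
    min_each_weight: 5

characteristic_rules:
  - name: binge_drinker
    set: finnish
    clauses:
      - - source: audit_c
          comparator: gt
          threshold: 7
          gender: male
      - - source: audit_c
          comparator: gt
          threshold: 4
          gender: female
  - name: popular
    set: finnish
    clauses:
      - - source: "metric:in_degree"
          comparator: ge
          threshold: 4
  - name: bad_influence
    set: finnish
    clauses:
      - - source: audit_c
          comparator: gt
          threshold: 4
        - source: "metric:degree"
          comparator: ge
          threshold: 4
  - name: binge_drinker
    set: spanish
    clauses:
      - - source: audit_c
          comparator: gt
          threshold: 4
  - name: popular
    set: spanish
    clauses:
      - - source: "metric:in_degree"
          comparator: ge
          threshold: 4
  - name: bad_influence
    set: spanish
    clauses:
      - - source: audit_c
          comparator: gt
          threshold: 4
        - source: "metric:degree"
          comparator: ge
          threshold: 4
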
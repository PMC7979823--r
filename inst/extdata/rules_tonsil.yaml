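# Tonsil gating strategy. Priorities: lower number evaluates first; the
# first satisfied rule assigns the type, unmatched cells become "others".
# ILC is evaluated first with an exclusive lineage gate so its assignment
# depends only on its own rule. Markers absent from a run's panel are
# trimmed at load time (negatives and any_of clauses only).
rules:
  - type: ILC
    priority: 1
    requires_positive: [CD45, CD127]
    requires_negative: [CD3, CD19, CD20, CD14, CD123, CD141, FceRIa]
  - type: B
    priority: 2
    requires_positive: [CD45, CD19]
    requires_negative: []
  - type: T_helper
    priority: 3
    requires_positive: [CD45, CD3, CD4]
    requires_negative: []
  - type: T_cytotoxic
    priority: 4
    requires_positive: [CD45, CD3, CD8]
    requires_negative: []
  - type: plasma
    priority: 5
    requires_positive: [CD138]
    requires_negative: []
  - type: myeloid
    priority: 6
    requires_positive: []
    requires_negative: []
    any_of:
      - [{marker: CD11c, sign: "+"}]
      - [{marker: CD14, sign: "+"}]
      - [{marker: CD56, sign: "-"}, {marker: CD16, sign: "+"}]
      - [{marker: CD141, sign: "+"}]
  - type: endothelial
    priority: 7
    requires_positive: [CD31]
    requires_negative: []
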
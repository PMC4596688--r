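# Default plus-orientation NES consensus classes.
# spacers are the counts of X (any residue) between consecutive Phi
# positions; a list entry with several values is a variable spacer.
# Phi alphabet defaults to [L, V, I, F, M].
patterns:
  - class_name: "1a"
    spacers: [3, 2, 1]
  - class_name: "1b"
    spacers: [2, 2, 1]
  - class_name: "1c"
    spacers: [3, 3, 1]
  - class_name: "1d"
    spacers: [2, 3, 1]
  - class_name: "2"
    spacers: [1, 2, 1]
  - class_name: "3"
    spacers:
      - [2, 3]
      - [2, 3]
      - [2]
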
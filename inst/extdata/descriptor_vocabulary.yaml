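# Closed descriptor vocabulary, version 1.
# Each field lists the complete set of options the report synthesizer may
# select from; free text is never generated for these fields.
skin_structure:
  - smooth
  - scaly
  - crusted
  - ulcerated
  - papular
  - plaque-like
image_color:
  - light brown
  - dark brown
  - black
  - pink
  - red
  - blue-gray
  - skin-colored
dermoscopic_structures:
  - pigment network
  - globules
  - streaks
  - dots
  - blue-whitish veil
  - arborizing vessels
  - regression structures
symmetry:
  - symmetric
  - asymmetric
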
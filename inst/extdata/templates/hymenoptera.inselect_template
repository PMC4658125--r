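# Example template for a pinned-Hymenoptera digitization project.
# Catalog numbers follow the nine-digit rule: exactly nine digits, no
# letters, no punctuation, no leading or trailing whitespace.
name: Hymenoptera
thumbnail_width: 4096
crop_filename:
  - Catalog number
fields:
  - name: Catalog number
    mandatory: true
    parser: regex
    pattern: '^[0-9]{9}$'
  - name: Location
    mandatory: true
    choices:
      - Africa
      - Americas
      - Asia
      - Europe
      - Oceania
  - name: Family
    mandatory: true
    choices:
      - Apidae
      - Formicidae
      - Ichneumonidae
      - Vespidae
  - name: Subfamily
    mandatory: true
    choices:
      - Apinae
      - Formicinae
      - Ichneumoninae
      - Myrmicinae
      - Vespinae
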
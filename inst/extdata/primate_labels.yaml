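# Branch rate-class labelling for the bundled 13-taxon primate fixture:
# class 1 = stem branch of the Old World monkeys (the focal branch),
# class 2 = hominoid crown clade (stem excluded by default).
- class: 1
  mrca: [Rhesus_macaque, Green_monkey]
  stem_only: true
- class: 2
  mrca: [Gibbon, Human]
  include_stem: false
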
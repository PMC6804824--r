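# Ordered decision list for aroma-group assignment.
# Each rule is evaluated against the five odor-class percentages
# (herbal, fruity, cool, floral, spicy) and the total emission (ug/g);
# the first rule whose 'when' expression is TRUE assigns its label.
# These defaults approximate the six lily aroma groups; group membership
# is not fully determined by class percentages, so edit freely.
- label: faint
  when: total < 1.0
- label: cool
  when: cool >= 40 && fruity < 20
- label: musky
  when: cool >= 20 && cool + fruity >= 55
- label: lily
  when: herbal >= 20 && fruity >= 35
- label: fruity
  when: fruity >= 55 && cool < 5 && herbal < 5
- label: fruity-honey
  when: fruity >= 40
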
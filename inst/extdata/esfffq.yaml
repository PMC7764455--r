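# Extended Short Form FFQ (ESFFFQ), 27 items, 8-level frequency scale.
#
# The vegetable target carries the published per-frequency gram
# contributions (salad and vegetables rows) and the 80 g / 240 g score
# cutoffs. Amount tables for the remaining targets of the instrument
# (fat, sugar, fiber, protein, salt) are not published and are therefore
# not part of this fixture; supply them in your own definition file or
# generate synthetic ones.
#
# Item provenance: the 19 tags from 'fruit' through 'fish' appear in the
# published subset ladder. The full 27-item list is not public; the last
# 8 tags (milk .. processedmeat) are RECONSTRUCTED from the parent
# instrument's food groups and are synthetic stand-ins, not verbatim
# instrument items.
name: ESFFFQ
scale:
  levels:
    - rarely or never
    - less than once a week
    - once a week
    - 2-3 times a week
    - 4-6 times a week
    - 1-2 times a day
    - 3-4 times a day
    - 5+ a day
items:
  - fruit
  - juice
  - salad
  - vegetables
  - chips
  - beans
  - fiber
  - wholebread
  - cheese
  - cakes
  - cream
  - grains
  - pizza
  - nuts_salt
  - nuts
  - potato
  - readmeat
  - whitemeat
  - fish
  - milk
  - yoghurt
  - eggs
  - sugardrinks
  - sweets
  - butter
  - pasta
  - processedmeat
targets:
  - name: vegetable
    direction: higher_better
    cutoffs: [80.0, 240.0]
    amounts:
      salad: [0.0, 4.0, 11.2, 28.8, 56.8, 120.0, 280.0, 480.0]
      vegetables: [0.0, 4.0, 11.2, 28.8, 56.8, 120.0, 280.0, 480.0]
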
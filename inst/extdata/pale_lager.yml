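# Default pale-lager pipeline configuration: attribute hierarchy, cohort
# definitions, fusion ratio and scale-construction parameters.
hierarchy:
  dimensions: [appearance, aroma, taste, drinking_sensation]
  children:
    appearance: [beer_color, clarity, foam_abundance]
    aroma: [malt, hop, fruit, floral, sweet, fermentation]
    taste: [sweetness, sourness, bitterness, umami, astringency]
    drinking_sensation: [smoothness, fullness, refreshment, body_coordination,
                         alcohol_warmth, persistence, prickliness, aftertaste,
                         foam_fineness]
  merge_map:
    hop_flower: [hop, floral]
    fruity_fermentation: [fruit, fermentation]
    aftertaste_persistence: [aftertaste, persistence]
  exclusions: [alcohol_warmth, appearance]
cohorts:
  - label: low
    min_occasions: 1
    max_occasions: 3
    frequency_factor: 2
    share: 0.3854
  - label: mid
    min_occasions: 4
    max_occasions: 8
    frequency_factor: 6
    share: 0.4249
  - label: high
    min_occasions: 9
    frequency_factor: 14
    share: 0.1897
alpha: 0.7
aggregate_layer: ahp
top_k: 3
survey_bounds: [1, 5]
tasting_bounds: [1, 9]
seed: 1
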
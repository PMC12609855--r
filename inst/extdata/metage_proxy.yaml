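# Linear metabolic-age proxy (years) for settings without a BIA device:
# metabolic_age = 0.541*age + 2.394*bmi - 7.326*male - 39.156
# This is a linear model, not a logistic one; it is applied by
# lipidval::impute_metabolic_age(), not by read_model().
name: metabolic-age linear proxy
outcome: metabolic_age_years
intercept: -39.156
terms:
  age: 0.541
  bmi: 2.394
  male: -7.326
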
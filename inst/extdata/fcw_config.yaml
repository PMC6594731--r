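# Run configuration for the regional case study.
base_year: 2016
horizon_years: 10
# annual net overseas / interstate migration, as fractions of the regional
# population (-0.006% and 0.058%)
nom_rate: -0.00006
nim_rate: 0.00058
rate_convention: destination
mode: published
assist_rate_overall: 0.3661
# annual CPI-style inflation used to deflate source-year prices to the base
# year; a config value, not an estimate of the framework itself
inflation_rate: 0.019
price_source_year: 2018
scenarios:
  - low
  - average
top_k: 4
seed: 20160630
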
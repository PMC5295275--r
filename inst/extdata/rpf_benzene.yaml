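# Benzene-index mixture: inhalation unit risks (per ug/m3) from IRIS.
# Benzene's published range collapses to its midpoint, 5.0e-6.
index_chemical: benzene
unit_risk:
  benzene: [2.2e-6, 7.8e-6]
  butadiene_13: 3.0e-5
  acetaldehyde: 2.2e-6
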
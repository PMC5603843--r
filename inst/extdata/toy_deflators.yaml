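# Synthetic consumer-price-index series (health-care basket, toy values)
# and 2013 CAD->USD purchasing-power-parity factor. Replace with official
# series for real analyses.
base_year: 2013
ppp: 0.81
cpi:
  2002: 100.0
  2003: 102.2
  2004: 104.0
  2005: 106.3
  2006: 108.4
  2007: 110.5
  2008: 113.0
  2009: 113.5
  2010: 115.5
  2011: 118.9
  2012: 120.6
  2013: 121.8
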
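waypoints:
- lat: 39.6536
  lon: -105.1932
  label: start
- lat: 39.6588161
  lon: -105.1932
  label: uphill_end
- lat: 39.6558243
  lon: -105.1885317
  label: top_end
sections:
- uphill
- top
- downhill
lengths_m:
  uphill: 580.0
  top: 520.0
  downhill: 470.0
slopes_deg:
  uphill: 4.0
  top: 2.0
  downhill: -6.0
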
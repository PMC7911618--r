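period,loss,gain,unchanged
2030_ssp126,0.01,17.68,40.74
2030_ssp245,0.002,22.80,40.73
2030_ssp585,0.002,24.08,40.73
2050_ssp126,2.15,28.58,38.60
2050_ssp245,0.05,40.95,40.70
2050_ssp585,0.002,48.07,40.73
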
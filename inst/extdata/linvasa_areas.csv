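period,highly,moderately,poorly,total
current,3.96,10.59,29.36,43.91
2030_ssp126,5.44,14.75,43.43,63.62
2030_ssp245,5.65,15.73,47.9,69.28
2030_ssp585,5.96,16.23,48.22,70.41
2050_ssp126,3.75,16.75,51.28,71.78
2050_ssp245,6.62,21.55,60.68,88.85
2050_ssp585,7.73,24.65,64.93,97.31
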
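year,s_adult,s_calf,pregnancy_rate,twinning_rate,prop_cows
2013,0.81,0.28,0.74,0.30,0.4502
2014,0.88,0.40,0.81,0.30,0.4487
2015,0.86,0.40,0.88,0.30,0.5044
2016,0.85,0.33,0.89,0.30,0.4904
2017,,,0.85,0.30,0.5234
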
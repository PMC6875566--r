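year,abundance,ci90_low,ci90_high,calf_fraction,bull_cow_ratio,twin_fraction
2013,2760,,,0.13,1.221,
2014,4350,,,0.15,1.229,
2015,3450,,,0.13,0.983,
2016,4020,,,0.17,1.039,
2017,3710,,,0.15,0.911,
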
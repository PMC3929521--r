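condition,spiked,measured,accuracy_pct
bench_top,0.1,0.096,96.0
bench_top,0.8,0.783,97.87
bench_top,1.6,1.571,98.18
bench_top,2.0,1.944,97.20
freeze_thaw,0.1,0.099,99.00
freeze_thaw,0.8,0.795,99.37
freeze_thaw,1.6,1.582,98.87
freeze_thaw,2.0,1.995,99.75
one_week,0.1,0.093,93.00
one_week,0.8,0.746,93.25
one_week,1.6,1.517,94.81
one_week,2.0,1.911,95.55
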
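arm,endpoint,time_months,survival_probability
TIL,PFS,3,0.792
TIL,PFS,6,0.612
TIL,PFS,9,0.485
TIL,PFS,12,0.395
TIL,OS,3,0.942
TIL,OS,6,0.871
TIL,OS,9,0.801
TIL,OS,12,0.735
Ipilimumab,PFS,3,0.635
Ipilimumab,PFS,6,0.269
Ipilimumab,PFS,9,0.129
Ipilimumab,PFS,12,0.072
Ipilimumab,OS,3,0.936
Ipilimumab,OS,6,0.847
Ipilimumab,OS,9,0.759
Ipilimumab,OS,12,0.679
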
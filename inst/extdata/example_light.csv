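# Step-change light protocol: 30 min at 100, then 2 h at 1000 umol m^-2 s^-1
time_s,ppfd_umol_m2_s
0,100
1799,100
1800,1000
9000,1000
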
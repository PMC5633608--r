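# Carbon conversion factors (fg C cell^-1), in-situ averages estimated from
# flow-cytometric cell size and carbon:volume relationships. Min/max retain
# the culture compilation's span (only averages were reported in situ).
set_label: in_situ
prochlorococcus: {min: 16, max: 53, average: 60}
synechococcus: {min: 170, max: 350, average: 154}
picoeukaryotes: {min: 800, max: 4400, average: 1319}
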
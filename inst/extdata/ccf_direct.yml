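# Carbon conversion factors (fg C cell^-1), unialgal-culture compilation.
set_label: direct
prochlorococcus: {min: 16, max: 53, average: 36}
synechococcus: {min: 170, max: 350, average: 255}
picoeukaryotes: {min: 800, max: 4400, average: 2590}
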
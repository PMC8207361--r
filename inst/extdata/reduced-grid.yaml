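# Reduced factorial design: both preference modes and landscapes, the ends
# and middle of the carrying-capacity schedule, all six fishing levels.
K: [5, 40, 160]
replicates: 10
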
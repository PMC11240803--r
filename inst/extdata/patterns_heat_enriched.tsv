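# condition: heat_enriched
# Reported sequential behaviour patterns, broilers in an enriched environment
# under heat stress (day 22, 30 C, n = 10 birds).
1.0 to 0.4	None
0.3	<{E,W,F}> (n = 3)
0.2	<{Ld,F}> (n = 2); <{Ld,W,D}> (n = 2); <{Ld,P,W,P}> (n = 2); <{E,W,D}> (n = 2); <{P,F,St,P}> (n = 2); <{E,F,E}> (n = 2); <{P,F,St,P} {E,W,F}> (n = 2)
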
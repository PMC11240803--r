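# condition: heat_plain
# Reported sequential behaviour patterns, broilers in a non-enriched
# environment under heat stress (day 22, 30 C, n = 10 birds).
1.0 to 0.5	None
0.4	<{Ld,P,W,D,W}> (n = 4)
0.3	<{Ld,P}> (n = 3); <{Ld,F,P}> (n = 3)
0.2	<{Ld,P,F}> (n = 2); <{Ld,P,St,Ll}> (n = 2); <{E,W,P,W,F}> (n = 2); <{Ld,P,St,Ll} {Ld,P,W,D,W}> (n = 2)
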
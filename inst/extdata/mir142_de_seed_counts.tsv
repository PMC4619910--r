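arm	quality	down	up
5p	exact	12	12
3p	exact	3	1
both	exact	2	1
5p	inexact	9	2
3p	inexact	5	1
both	inexact	12	3
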
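arm	quality	mir_null	mir_142	genome
5p	exact	9	6	2914
3p	exact	1	2	720
both	exact	0	0	387
5p	inexact	7	7	3644
3p	inexact	7	8	2520
both	inexact	9	4	4820
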
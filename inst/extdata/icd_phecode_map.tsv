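icd	flag	phecode
008.45	9	008
A04.7	10	008
041.12	9	041
B95.62	10	041
276.1	9	276.1
E87.1	10	276.1
276.9	9	276.1
276.9	9	585.3
286.3	9	286.1
D68.2	10	286.1
288.01	9	288.1
D70.4	10	288.1
296.20	9	296.2
F32.9	10	296.2
317	9	317
F70	10	317
327.23	9	327.3
G47.33	10	327.3
401.9	9	401.1
I10	10	401.1
427.31	9	427.2
I48.91	10	427.2
480.9	9	480.1
J12.89	10	480.1
493.90	9	495
J45.909	10	495
494.0	9	499
J47.9	10	499
277.00	9	499
E84.9	10	499
507.0	9	507
J69.0	10	507
530.11	9	530.1
K21.0	10	530.1
579.9	9	557
K90.9	10	557
571.5	9	571.5
K74.60	10	571.5
585.3	9	585.3
N18.3	10	585.3
754.30	9	740.1
Q65.0	10	740.1
945.20	9	945
T24.0	10	945
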
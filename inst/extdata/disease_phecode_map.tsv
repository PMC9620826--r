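disease_id	phecode
OMIM:219700	499
OMIM:219700	480.1
OMIM:219700	495
OMIM:219700	276.1
OMIM:219700	557
OMIM:613490	571.5
OMIM:613490	507
OMIM:613490	495
OMIM:613490	286.1
OMIM:174900	557
OMIM:174900	530.1
OMIM:174900	008
OMIM:145600	327.3
OMIM:145600	740.1
OMIM:145600	945
OMIM:145600	296.2
OMIM:210000	288.1
OMIM:210000	041
OMIM:210000	317
OMIM:210000	427.2
OMIM:210000	401.1
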
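hpo_term_id	phecode	match_quality
HP:0006528	499	broader
HP:0002205	480.1	broader
HP:0012735	495	broader
HP:0001508	276.1	broader
HP:0002024	557	exact
HP:0001399	571.5	exact
HP:0006532	507	broader
HP:0002097	495	broader
HP:0003010	286.1	broader
HP:0001903	288.1	broader
HP:0002716	041	broader
HP:0001249	317	exact
HP:0002189	327.3	broader
HP:0000822	401.1	exact
HP:0011675	427.2	broader
HP:0002014	557	broader
HP:0002580	530.1	broader
HP:0004396	008	broader
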
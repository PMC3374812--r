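sample_id	17q22	8q24.3	8p11.2	odx_score
T01	amplified	amplified	amplified	46
T02	not amplified	not amplified	amplified	42
T03	borderline	not amplified	amplified	38
T04	amplified	borderline	borderline	36
T05	borderline	amplified	borderline	33
T06	amplified	amplified	amplified	44
T07	amplified	amplified	borderline	42
T08	borderline	borderline	borderline	34
T09	no signal	not amplified	not amplified	13
T10	no signal	not amplified	not amplified	8
T11	not amplified	not amplified	not amplified	5
T12	borderline	not amplified	not amplified	12
T13	not amplified	no signal	no signal	11
T14	not amplified	not amplified	not amplified	11
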
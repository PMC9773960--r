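participant_id,valence,ra_summary
p001,positive,3.3
p001,negative,2.1
p002,positive,1.3
p002,negative,1.3
p003,positive,2.1
p003,negative,1.5
p004,positive,3.7
p004,negative,1.3
p005,positive,4
p005,negative,1.9
p006,positive,2.8
p006,negative,1.6
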
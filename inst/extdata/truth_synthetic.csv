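participant_id,valence,strategy,true_summary_value,low_completion
p001,positive,peak_end,3.166666666666667,FALSE
p001,negative,peak_end,2,FALSE
p002,positive,noisy_mean,1.263157894736842,FALSE
p002,negative,noisy_mean,1.2894736842105263,FALSE
p003,positive,mean,2.051282051282051,FALSE
p003,negative,mean,1.4871794871794872,FALSE
p004,positive,mean,3.707317073170732,FALSE
p004,negative,mean,1.3157894736842106,FALSE
p005,positive,noisy_mean,3.8636363636363638,TRUE
p005,negative,noisy_mean,1.7857142857142858,TRUE
p006,positive,mean,2.75,FALSE
p006,negative,mean,1.6486486486486487,FALSE
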
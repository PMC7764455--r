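respondent,salad,vegetables,fruit,juice
r1,1-2 times a day,4-6 times a week,once a week,rarely or never
r2,rarely or never,3-4 times a day,2-3 times a week,
r3,0,7,5,3
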
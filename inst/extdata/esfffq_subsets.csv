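subset,item
F1,fruit
F1,juice
F1,salad
F1,vegetables
F1,chips
F1,beans
F1,fiber
F1,wholebread
F1,cheese
F1,cakes
F1,cream
F1,grains
F1,pizza
F1,nuts_salt
F1,nuts
F1,potato
F1,readmeat
F1,whitemeat
F1,fish
F2,fruit
F2,juice
F2,salad
F2,vegetables
F2,chips
F2,beans
F2,fiber
F2,wholebread
F2,cheese
F2,cakes
F2,grains
F2,nuts
F2,potato
F2,readmeat
F2,whitemeat
F2,fish
F3,fruit
F3,juice
F3,salad
F3,beans
F3,fiber
F3,wholebread
F3,grains
F3,nuts
F3,readmeat
F3,whitemeat
F4,fruit
F4,juice
F4,salad
F4,fiber
F4,wholebread
F4,grains
F5,fruit
F5,juice
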
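"pair_id","delta_p","mtdna_relative_time"
"pair01",91.0377703700215,0.0143553896248341
"pair02",135.858086338267,0.00682050680369139
"pair03",130.654204357415,0.01594823589921
"pair04",93.2603766955435,0.0208801404349506
"pair05",146.428493391722,0.01355989735201
"pair06",152.536011338234,0.0204658250249922
"pair07",146.822892334312,0.0157428409643471
"pair08",112.946243174374,0.0097132433950901
"pair09",82.3101998586208,0.0107338077537715
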
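"assessor_id","study_id","bias_id","nature","action","mean","variance"
"A1","S1","rigor","internal","additive",0.0551542726687509,0.02
"A2","S1","rigor","internal","additive",0.109242459232337,0.02
"A3","S1","rigor","internal","additive",0.179392266560441,0.02
"A1","S2","rigor","internal","additive",0.0434812162876857,0.02
"A2","S2","rigor","internal","additive",0.0959874121724505,0.02
"A3","S2","rigor","internal","additive",0.106621014219055,0.02
"A1","S3","rigor","internal","additive",0.135397736463587,0.02
"A2","S3","rigor","internal","additive",0.088015098791408,0.02
"A3","S3","rigor","internal","additive",0.199223696832646,0.02
"A1","S4","rigor","internal","additive",0.0930606493940168,0.02
"A2","S4","rigor","internal","additive",0.120882537539628,0.02
"A3","S4","rigor","internal","additive",0.149087638873183,0.02
"A1","S5","rigor","internal","additive",0.0803652322248094,0.02
"A2","S5","rigor","internal","additive",0.0480165511525543,0.02
"A3","S5","rigor","internal","additive",0.189111448015429,0.02
"A1","S6","rigor","internal","additive",-0.0155534542302583,0.02
"A2","S6","rigor","internal","additive",0.143930229046063,0.02
"A3","S6","rigor","internal","additive",0.101790335900761,0.02
"A1","S7","rigor","internal","additive",0.150641434606354,0.02
"A2","S7","rigor","internal","additive",0.121613257726981,0.02
"A3","S7","rigor","internal","additive",0.204540960262457,0.02
"A1","S8","rigor","internal","additive",0.0400037090178064,0.02
"A2","S8","rigor","internal","additive",0.179481910014504,0.02
"A3","S8","rigor","internal","additive",0.197732582111163,0.02
"A1","S1","relevance","external","proportional",0.900246888841407,0.02
"A2","S1","relevance","external","proportional",0.777414680607694,0.02
"A3","S1","relevance","external","proportional",0.923861865130681,0.02
"A1","S2","relevance","external","proportional",0.87017209156843,0.02
"A2","S2","relevance","external","proportional",0.939610163514982,0.02
"A3","S2","relevance","external","proportional",0.914481835508867,0.02
"A1","S3","relevance","external","proportional",0.936946930188106,0.02
"A2","S3","relevance","external","proportional",0.915948020054882,0.02
"A3","S3","relevance","external","proportional",0.9538082176906,0.02
"A1","S4","relevance","external","proportional",0.885792113975588,0.02
"A2","S4","relevance","external","proportional",0.861166236301012,0.02
"A3","S4","relevance","external","proportional",0.870216975065411,0.02
"A1","S5","relevance","external","proportional",0.813701011042698,0.02
"A2","S5","relevance","external","proportional",0.854870776011816,0.02
"A3","S5","relevance","external","proportional",0.872046904254977,0.02
"A1","S6","relevance","external","proportional",0.887674371633324,0.02
"A2","S6","relevance","external","proportional",0.880820688578428,0.02
"A3","S6","relevance","external","proportional",0.802044841241644,0.02
"A1","S7","relevance","external","proportional",0.85791474699322,0.02
"A2","S7","relevance","external","proportional",0.995177373367382,0.02
"A3","S7","relevance","external","proportional",0.931124696506037,0.02
"A1","S8","relevance","external","proportional",0.999546021779016,0.02
"A2","S8","relevance","external","proportional",0.884725813757927,0.02
"A3","S8","relevance","external","proportional",0.895457788239962,0.02
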
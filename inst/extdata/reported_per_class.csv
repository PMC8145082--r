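scope,rater,class,precision,recall,f1,support
overall,classifier,SG+D,0.79,0.82,0.81,1189
overall,classifier,D,0.92,0.86,0.89,2425
overall,classifier,SG,0.64,0.63,0.63,228
overall,classifier,Other,0.24,0.67,0.35,79
overall,coder,SG+D,0.78,0.84,0.81,1189
overall,coder,D,0.91,0.90,0.90,2425
overall,coder,SG,0.71,0.45,0.55,228
overall,coder,Other,0.35,0.38,0.36,79
semi-inclusive,classifier,SG+D,0.76,0.83,0.79,702
semi-inclusive,classifier,D,0.92,0.80,0.86,1157
semi-inclusive,classifier,SG,0.40,0.57,0.47,69
semi-inclusive,classifier,Other,0.16,0.50,0.24,30
semi-inclusive,coder,SG+D,0.81,0.82,0.82,702
semi-inclusive,coder,D,0.88,0.88,0.88,1157
semi-inclusive,coder,SG,0.61,0.36,0.45,69
semi-inclusive,coder,Other,0.17,0.30,0.21,30
fully-inclusive,classifier,SG+D,0.86,0.81,0.83,487
fully-inclusive,classifier,D,0.93,0.91,0.92,1268
fully-inclusive,classifier,SG,0.83,0.65,0.73,159
fully-inclusive,classifier,Other,0.29,0.78,0.42,49
fully-inclusive,coder,SG+D,0.75,0.86,0.80,487
fully-inclusive,coder,D,0.93,0.92,0.93,1268
fully-inclusive,coder,SG,0.74,0.49,0.59,159
fully-inclusive,coder,Other,0.66,0.43,0.52,49
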
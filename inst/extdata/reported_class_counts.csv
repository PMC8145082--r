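scope,class,count,total
overall,D,2415,3921
overall,SG+D,1189,3921
semi-inclusive,D,1157,1958
semi-inclusive,SG+D,702,1958
fully-inclusive,D,1268,1963
fully-inclusive,SG+D,487,1963
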
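scope,rater,total_errors,transition_errors
semi-inclusive,classifier,400,65
fully-inclusive,classifier,272,45
semi-inclusive,coder,329,73
fully-inclusive,coder,274,61
overall,classifier,672,110
overall,coder,603,134
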
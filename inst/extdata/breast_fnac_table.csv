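test_result,hist_dpos,hist_dneg,fu_dpos,fu_dneg,lost
positive,803,1,12,0,26
suspect,120,31,0,1,2
negative,24,115,1,471,160
insufficient,18,26,0,6,3
total,965,173,13,478,191
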
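"name","kind","params","state"
"conv1","conv",448,0
"conv2","conv",4640,0
"conv3","conv",18496,0
"conv4","conv",73856,0
"dense1","dense",2560032,0
"dense2","dense",528,0
"predictions","dense",51,0
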
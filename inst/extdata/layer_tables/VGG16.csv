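"name","kind","params","state"
"conv1","conv",1792,0
"conv2","conv",36928,0
"conv3","conv",73856,0
"conv4","conv",147584,0
"conv5","conv",295168,0
"conv6","conv",590080,0
"conv7","conv",590080,0
"conv8","conv",1180160,0
"conv9","conv",2359808,0
"conv10","conv",2359808,0
"conv11","conv",2359808,0
"conv12","conv",2359808,0
"conv13","conv",2359808,0
"fc1","dense",102764544,0
"fc2","dense",16781312,0
"predictions","dense",12291,0
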
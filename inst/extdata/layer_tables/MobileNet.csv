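"name","kind","params","state"
"conv1","conv",864,0
"conv1_bn","batch_norm",64,64
"block1_dw","depthwise_conv",288,0
"block1_dw_bn","batch_norm",64,64
"block1_pw","conv",2048,0
"block1_pw_bn","batch_norm",128,128
"block2_dw","depthwise_conv",576,0
"block2_dw_bn","batch_norm",128,128
"block2_pw","conv",8192,0
"block2_pw_bn","batch_norm",256,256
"block3_dw","depthwise_conv",1152,0
"block3_dw_bn","batch_norm",256,256
"block3_pw","conv",16384,0
"block3_pw_bn","batch_norm",256,256
"block4_dw","depthwise_conv",1152,0
"block4_dw_bn","batch_norm",256,256
"block4_pw","conv",32768,0
"block4_pw_bn","batch_norm",512,512
"block5_dw","depthwise_conv",2304,0
"block5_dw_bn","batch_norm",512,512
"block5_pw","conv",65536,0
"block5_pw_bn","batch_norm",512,512
"block6_dw","depthwise_conv",2304,0
"block6_dw_bn","batch_norm",512,512
"block6_pw","conv",131072,0
"block6_pw_bn","batch_norm",1024,1024
"block7_dw","depthwise_conv",4608,0
"block7_dw_bn","batch_norm",1024,1024
"block7_pw","conv",262144,0
"block7_pw_bn","batch_norm",1024,1024
"block8_dw","depthwise_conv",4608,0
"block8_dw_bn","batch_norm",1024,1024
"block8_pw","conv",262144,0
"block8_pw_bn","batch_norm",1024,1024
"block9_dw","depthwise_conv",4608,0
"block9_dw_bn","batch_norm",1024,1024
"block9_pw","conv",262144,0
"block9_pw_bn","batch_norm",1024,1024
"block10_dw","depthwise_conv",4608,0
"block10_dw_bn","batch_norm",1024,1024
"block10_pw","conv",262144,0
"block10_pw_bn","batch_norm",1024,1024
"block11_dw","depthwise_conv",4608,0
"block11_dw_bn","batch_norm",1024,1024
"block11_pw","conv",262144,0
"block11_pw_bn","batch_norm",1024,1024
"block12_dw","depthwise_conv",4608,0
"block12_dw_bn","batch_norm",1024,1024
"block12_pw","conv",524288,0
"block12_pw_bn","batch_norm",2048,2048
"block13_dw","depthwise_conv",9216,0
"block13_dw_bn","batch_norm",2048,2048
"block13_pw","conv",1048576,0
"block13_pw_bn","batch_norm",2048,2048
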
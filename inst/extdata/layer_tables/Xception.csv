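"name","kind","params","state"
"block1_conv1","conv",864,0
"block1_conv1_bn","batch_norm",64,64
"block1_conv2","conv",18432,0
"block1_conv2_bn","batch_norm",128,128
"block2_sepconv1","separable_conv",8768,0
"block2_sepconv1_bn","batch_norm",256,256
"block2_sepconv2","separable_conv",17536,0
"block2_sepconv2_bn","batch_norm",256,256
"block2_residual","conv",8192,0
"block2_residual_bn","batch_norm",256,256
"block3_sepconv1","separable_conv",33920,0
"block3_sepconv1_bn","batch_norm",512,512
"block3_sepconv2","separable_conv",67840,0
"block3_sepconv2_bn","batch_norm",512,512
"block3_residual","conv",32768,0
"block3_residual_bn","batch_norm",512,512
"block4_sepconv1","separable_conv",188672,0
"block4_sepconv1_bn","batch_norm",1456,1456
"block4_sepconv2","separable_conv",536536,0
"block4_sepconv2_bn","batch_norm",1456,1456
"block4_residual","conv",186368,0
"block4_residual_bn","batch_norm",1456,1456
"block5_sepconv1","separable_conv",536536,0
"block5_sepconv1_bn","batch_norm",1456,1456
"block5_sepconv2","separable_conv",536536,0
"block5_sepconv2_bn","batch_norm",1456,1456
"block5_sepconv3","separable_conv",536536,0
"block5_sepconv3_bn","batch_norm",1456,1456
"block6_sepconv1","separable_conv",536536,0
"block6_sepconv1_bn","batch_norm",1456,1456
"block6_sepconv2","separable_conv",536536,0
"block6_sepconv2_bn","batch_norm",1456,1456
"block6_sepconv3","separable_conv",536536,0
"block6_sepconv3_bn","batch_norm",1456,1456
"block7_sepconv1","separable_conv",536536,0
"block7_sepconv1_bn","batch_norm",1456,1456
"block7_sepconv2","separable_conv",536536,0
"block7_sepconv2_bn","batch_norm",1456,1456
"block7_sepconv3","separable_conv",536536,0
"block7_sepconv3_bn","batch_norm",1456,1456
"block8_sepconv1","separable_conv",536536,0
"block8_sepconv1_bn","batch_norm",1456,1456
"block8_sepconv2","separable_conv",536536,0
"block8_sepconv2_bn","batch_norm",1456,1456
"block8_sepconv3","separable_conv",536536,0
"block8_sepconv3_bn","batch_norm",1456,1456
"block9_sepconv1","separable_conv",536536,0
"block9_sepconv1_bn","batch_norm",1456,1456
"block9_sepconv2","separable_conv",536536,0
"block9_sepconv2_bn","batch_norm",1456,1456
"block9_sepconv3","separable_conv",536536,0
"block9_sepconv3_bn","batch_norm",1456,1456
"block10_sepconv1","separable_conv",536536,0
"block10_sepconv1_bn","batch_norm",1456,1456
"block10_sepconv2","separable_conv",536536,0
"block10_sepconv2_bn","batch_norm",1456,1456
"block10_sepconv3","separable_conv",536536,0
"block10_sepconv3_bn","batch_norm",1456,1456
"block11_sepconv1","separable_conv",536536,0
"block11_sepconv1_bn","batch_norm",1456,1456
"block11_sepconv2","separable_conv",536536,0
"block11_sepconv2_bn","batch_norm",1456,1456
"block11_sepconv3","separable_conv",536536,0
"block11_sepconv3_bn","batch_norm",1456,1456
"block12_sepconv1","separable_conv",536536,0
"block12_sepconv1_bn","batch_norm",1456,1456
"block12_sepconv2","separable_conv",536536,0
"block12_sepconv2_bn","batch_norm",1456,1456
"block12_sepconv3","separable_conv",536536,0
"block12_sepconv3_bn","batch_norm",1456,1456
"block13_sepconv1","separable_conv",536536,0
"block13_sepconv1_bn","batch_norm",1456,1456
"block13_sepconv2","separable_conv",752024,0
"block13_sepconv2_bn","batch_norm",2048,2048
"block13_residual","conv",745472,0
"block13_residual_bn","batch_norm",2048,2048
"block14_sepconv1","separable_conv",1582080,0
"block14_sepconv1_bn","batch_norm",3072,3072
"block14_sepconv2","separable_conv",3159552,0
"block14_sepconv2_bn","batch_norm",4096,4096
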
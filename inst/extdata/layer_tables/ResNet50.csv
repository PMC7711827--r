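"name","kind","params","state"
"conv1","conv",9472,0
"conv1_bn","batch_norm",128,128
"stage1_block1_conv1","conv",4160,0
"stage1_block1_conv1_bn","batch_norm",128,128
"stage1_block1_conv2","conv",36928,0
"stage1_block1_conv2_bn","batch_norm",128,128
"stage1_block1_conv3","conv",16640,0
"stage1_block1_conv3_bn","batch_norm",512,512
"stage1_block1_shortcut","conv",16640,0
"stage1_block1_shortcut_bn","batch_norm",512,512
"stage1_block2_conv1","conv",16448,0
"stage1_block2_conv1_bn","batch_norm",128,128
"stage1_block2_conv2","conv",36928,0
"stage1_block2_conv2_bn","batch_norm",128,128
"stage1_block2_conv3","conv",16640,0
"stage1_block2_conv3_bn","batch_norm",512,512
"stage1_block3_conv1","conv",16448,0
"stage1_block3_conv1_bn","batch_norm",128,128
"stage1_block3_conv2","conv",36928,0
"stage1_block3_conv2_bn","batch_norm",128,128
"stage1_block3_conv3","conv",16640,0
"stage1_block3_conv3_bn","batch_norm",512,512
"stage2_block1_conv1","conv",32896,0
"stage2_block1_conv1_bn","batch_norm",256,256
"stage2_block1_conv2","conv",147584,0
"stage2_block1_conv2_bn","batch_norm",256,256
"stage2_block1_conv3","conv",66048,0
"stage2_block1_conv3_bn","batch_norm",1024,1024
"stage2_block1_shortcut","conv",131584,0
"stage2_block1_shortcut_bn","batch_norm",1024,1024
"stage2_block2_conv1","conv",65664,0
"stage2_block2_conv1_bn","batch_norm",256,256
"stage2_block2_conv2","conv",147584,0
"stage2_block2_conv2_bn","batch_norm",256,256
"stage2_block2_conv3","conv",66048,0
"stage2_block2_conv3_bn","batch_norm",1024,1024
"stage2_block3_conv1","conv",65664,0
"stage2_block3_conv1_bn","batch_norm",256,256
"stage2_block3_conv2","conv",147584,0
"stage2_block3_conv2_bn","batch_norm",256,256
"stage2_block3_conv3","conv",66048,0
"stage2_block3_conv3_bn","batch_norm",1024,1024
"stage2_block4_conv1","conv",65664,0
"stage2_block4_conv1_bn","batch_norm",256,256
"stage2_block4_conv2","conv",147584,0
"stage2_block4_conv2_bn","batch_norm",256,256
"stage2_block4_conv3","conv",66048,0
"stage2_block4_conv3_bn","batch_norm",1024,1024
"stage3_block1_conv1","conv",131328,0
"stage3_block1_conv1_bn","batch_norm",512,512
"stage3_block1_conv2","conv",590080,0
"stage3_block1_conv2_bn","batch_norm",512,512
"stage3_block1_conv3","conv",263168,0
"stage3_block1_conv3_bn","batch_norm",2048,2048
"stage3_block1_shortcut","conv",525312,0
"stage3_block1_shortcut_bn","batch_norm",2048,2048
"stage3_block2_conv1","conv",262400,0
"stage3_block2_conv1_bn","batch_norm",512,512
"stage3_block2_conv2","conv",590080,0
"stage3_block2_conv2_bn","batch_norm",512,512
"stage3_block2_conv3","conv",263168,0
"stage3_block2_conv3_bn","batch_norm",2048,2048
"stage3_block3_conv1","conv",262400,0
"stage3_block3_conv1_bn","batch_norm",512,512
"stage3_block3_conv2","conv",590080,0
"stage3_block3_conv2_bn","batch_norm",512,512
"stage3_block3_conv3","conv",263168,0
"stage3_block3_conv3_bn","batch_norm",2048,2048
"stage3_block4_conv1","conv",262400,0
"stage3_block4_conv1_bn","batch_norm",512,512
"stage3_block4_conv2","conv",590080,0
"stage3_block4_conv2_bn","batch_norm",512,512
"stage3_block4_conv3","conv",263168,0
"stage3_block4_conv3_bn","batch_norm",2048,2048
"stage3_block5_conv1","conv",262400,0
"stage3_block5_conv1_bn","batch_norm",512,512
"stage3_block5_conv2","conv",590080,0
"stage3_block5_conv2_bn","batch_norm",512,512
"stage3_block5_conv3","conv",263168,0
"stage3_block5_conv3_bn","batch_norm",2048,2048
"stage3_block6_conv1","conv",262400,0
"stage3_block6_conv1_bn","batch_norm",512,512
"stage3_block6_conv2","conv",590080,0
"stage3_block6_conv2_bn","batch_norm",512,512
"stage3_block6_conv3","conv",263168,0
"stage3_block6_conv3_bn","batch_norm",2048,2048
"stage4_block1_conv1","conv",524800,0
"stage4_block1_conv1_bn","batch_norm",1024,1024
"stage4_block1_conv2","conv",2359808,0
"stage4_block1_conv2_bn","batch_norm",1024,1024
"stage4_block1_conv3","conv",1050624,0
"stage4_block1_conv3_bn","batch_norm",4096,4096
"stage4_block1_shortcut","conv",2099200,0
"stage4_block1_shortcut_bn","batch_norm",4096,4096
"stage4_block2_conv1","conv",1049088,0
"stage4_block2_conv1_bn","batch_norm",1024,1024
"stage4_block2_conv2","conv",2359808,0
"stage4_block2_conv2_bn","batch_norm",1024,1024
"stage4_block2_conv3","conv",1050624,0
"stage4_block2_conv3_bn","batch_norm",4096,4096
"stage4_block3_conv1","conv",1049088,0
"stage4_block3_conv1_bn","batch_norm",1024,1024
"stage4_block3_conv2","conv",2359808,0
"stage4_block3_conv2_bn","batch_norm",1024,1024
"stage4_block3_conv3","conv",1050624,0
"stage4_block3_conv3_bn","batch_norm",4096,4096
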
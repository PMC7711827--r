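"name","kind","params","state"
"stem1","conv",864,0
"stem1_bn","batch_norm",32,64
"stem2","conv",9216,0
"stem2_bn","batch_norm",32,64
"stem3","conv",18432,0
"stem3_bn","batch_norm",64,128
"stem4","conv",5120,0
"stem4_bn","batch_norm",80,160
"stem5","conv",138240,0
"stem5_bn","batch_norm",192,384
"mixed0_1x1","conv",12288,0
"mixed0_1x1_bn","batch_norm",64,128
"mixed0_5x5_1","conv",9216,0
"mixed0_5x5_1_bn","batch_norm",48,96
"mixed0_5x5_2","conv",76800,0
"mixed0_5x5_2_bn","batch_norm",64,128
"mixed0_dbl_1","conv",12288,0
"mixed0_dbl_1_bn","batch_norm",64,128
"mixed0_dbl_2","conv",55296,0
"mixed0_dbl_2_bn","batch_norm",96,192
"mixed0_dbl_3","conv",82944,0
"mixed0_dbl_3_bn","batch_norm",96,192
"mixed0_pool","conv",6144,0
"mixed0_pool_bn","batch_norm",32,64
"mixed1_1x1","conv",16384,0
"mixed1_1x1_bn","batch_norm",64,128
"mixed1_5x5_1","conv",12288,0
"mixed1_5x5_1_bn","batch_norm",48,96
"mixed1_5x5_2","conv",76800,0
"mixed1_5x5_2_bn","batch_norm",64,128
"mixed1_dbl_1","conv",16384,0
"mixed1_dbl_1_bn","batch_norm",64,128
"mixed1_dbl_2","conv",55296,0
"mixed1_dbl_2_bn","batch_norm",96,192
"mixed1_dbl_3","conv",82944,0
"mixed1_dbl_3_bn","batch_norm",96,192
"mixed1_pool","conv",16384,0
"mixed1_pool_bn","batch_norm",64,128
"mixed2_1x1","conv",18432,0
"mixed2_1x1_bn","batch_norm",64,128
"mixed2_5x5_1","conv",13824,0
"mixed2_5x5_1_bn","batch_norm",48,96
"mixed2_5x5_2","conv",76800,0
"mixed2_5x5_2_bn","batch_norm",64,128
"mixed2_dbl_1","conv",18432,0
"mixed2_dbl_1_bn","batch_norm",64,128
"mixed2_dbl_2","conv",55296,0
"mixed2_dbl_2_bn","batch_norm",96,192
"mixed2_dbl_3","conv",82944,0
"mixed2_dbl_3_bn","batch_norm",96,192
"mixed2_pool","conv",18432,0
"mixed2_pool_bn","batch_norm",64,128
"mixed3_3x3","conv",995328,0
"mixed3_3x3_bn","batch_norm",384,768
"mixed3_dbl_1","conv",18432,0
"mixed3_dbl_1_bn","batch_norm",64,128
"mixed3_dbl_2","conv",55296,0
"mixed3_dbl_2_bn","batch_norm",96,192
"mixed3_dbl_3","conv",82944,0
"mixed3_dbl_3_bn","batch_norm",96,192
"mixed4_1x1","conv",147456,0
"mixed4_1x1_bn","batch_norm",192,384
"mixed4_7x7_1","conv",98304,0
"mixed4_7x7_1_bn","batch_norm",128,256
"mixed4_7x7_2","conv",114688,0
"mixed4_7x7_2_bn","batch_norm",128,256
"mixed4_7x7_3","conv",172032,0
"mixed4_7x7_3_bn","batch_norm",192,384
"mixed4_dbl_1","conv",98304,0
"mixed4_dbl_1_bn","batch_norm",128,256
"mixed4_dbl_2","conv",114688,0
"mixed4_dbl_2_bn","batch_norm",128,256
"mixed4_dbl_3","conv",114688,0
"mixed4_dbl_3_bn","batch_norm",128,256
"mixed4_dbl_4","conv",114688,0
"mixed4_dbl_4_bn","batch_norm",128,256
"mixed4_dbl_5","conv",172032,0
"mixed4_dbl_5_bn","batch_norm",192,384
"mixed4_pool","conv",147456,0
"mixed4_pool_bn","batch_norm",192,384
"mixed5_1x1","conv",147456,0
"mixed5_1x1_bn","batch_norm",192,384
"mixed5_7x7_1","conv",122880,0
"mixed5_7x7_1_bn","batch_norm",160,320
"mixed5_7x7_2","conv",179200,0
"mixed5_7x7_2_bn","batch_norm",160,320
"mixed5_7x7_3","conv",215040,0
"mixed5_7x7_3_bn","batch_norm",192,384
"mixed5_dbl_1","conv",122880,0
"mixed5_dbl_1_bn","batch_norm",160,320
"mixed5_dbl_2","conv",179200,0
"mixed5_dbl_2_bn","batch_norm",160,320
"mixed5_dbl_3","conv",179200,0
"mixed5_dbl_3_bn","batch_norm",160,320
"mixed5_dbl_4","conv",179200,0
"mixed5_dbl_4_bn","batch_norm",160,320
"mixed5_dbl_5","conv",215040,0
"mixed5_dbl_5_bn","batch_norm",192,384
"mixed5_pool","conv",147456,0
"mixed5_pool_bn","batch_norm",192,384
"mixed6_1x1","conv",147456,0
"mixed6_1x1_bn","batch_norm",192,384
"mixed6_7x7_1","conv",122880,0
"mixed6_7x7_1_bn","batch_norm",160,320
"mixed6_7x7_2","conv",179200,0
"mixed6_7x7_2_bn","batch_norm",160,320
"mixed6_7x7_3","conv",215040,0
"mixed6_7x7_3_bn","batch_norm",192,384
"mixed6_dbl_1","conv",122880,0
"mixed6_dbl_1_bn","batch_norm",160,320
"mixed6_dbl_2","conv",179200,0
"mixed6_dbl_2_bn","batch_norm",160,320
"mixed6_dbl_3","conv",179200,0
"mixed6_dbl_3_bn","batch_norm",160,320
"mixed6_dbl_4","conv",179200,0
"mixed6_dbl_4_bn","batch_norm",160,320
"mixed6_dbl_5","conv",215040,0
"mixed6_dbl_5_bn","batch_norm",192,384
"mixed6_pool","conv",147456,0
"mixed6_pool_bn","batch_norm",192,384
"mixed7_1x1","conv",147456,0
"mixed7_1x1_bn","batch_norm",192,384
"mixed7_7x7_1","conv",147456,0
"mixed7_7x7_1_bn","batch_norm",192,384
"mixed7_7x7_2","conv",258048,0
"mixed7_7x7_2_bn","batch_norm",192,384
"mixed7_7x7_3","conv",258048,0
"mixed7_7x7_3_bn","batch_norm",192,384
"mixed7_dbl_1","conv",147456,0
"mixed7_dbl_1_bn","batch_norm",192,384
"mixed7_dbl_2","conv",258048,0
"mixed7_dbl_2_bn","batch_norm",192,384
"mixed7_dbl_3","conv",258048,0
"mixed7_dbl_3_bn","batch_norm",192,384
"mixed7_dbl_4","conv",258048,0
"mixed7_dbl_4_bn","batch_norm",192,384
"mixed7_dbl_5","conv",258048,0
"mixed7_dbl_5_bn","batch_norm",192,384
"mixed7_pool","conv",147456,0
"mixed7_pool_bn","batch_norm",192,384
"mixed8_3x3_1","conv",147456,0
"mixed8_3x3_1_bn","batch_norm",192,384
"mixed8_3x3_2","conv",552960,0
"mixed8_3x3_2_bn","batch_norm",320,640
"mixed8_7x7_1","conv",147456,0
"mixed8_7x7_1_bn","batch_norm",192,384
"mixed8_7x7_2","conv",258048,0
"mixed8_7x7_2_bn","batch_norm",192,384
"mixed8_7x7_3","conv",258048,0
"mixed8_7x7_3_bn","batch_norm",192,384
"mixed8_7x7_4","conv",331776,0
"mixed8_7x7_4_bn","batch_norm",192,384
"mixed9_1x1","conv",409600,0
"mixed9_1x1_bn","batch_norm",320,640
"mixed9_3x3_1","conv",491520,0
"mixed9_3x3_1_bn","batch_norm",384,768
"mixed9_3x3_2a","conv",442368,0
"mixed9_3x3_2a_bn","batch_norm",384,768
"mixed9_3x3_2b","conv",442368,0
"mixed9_3x3_2b_bn","batch_norm",384,768
"mixed9_dbl_1","conv",573440,0
"mixed9_dbl_1_bn","batch_norm",448,896
"mixed9_dbl_2","conv",1548288,0
"mixed9_dbl_2_bn","batch_norm",384,768
"mixed9_dbl_3a","conv",442368,0
"mixed9_dbl_3a_bn","batch_norm",384,768
"mixed9_dbl_3b","conv",442368,0
"mixed9_dbl_3b_bn","batch_norm",384,768
"mixed9_pool","conv",245760,0
"mixed9_pool_bn","batch_norm",192,384
"mixed10_1x1","conv",655360,0
"mixed10_1x1_bn","batch_norm",320,640
"mixed10_3x3_1","conv",786432,0
"mixed10_3x3_1_bn","batch_norm",384,768
"mixed10_3x3_2a","conv",442368,0
"mixed10_3x3_2a_bn","batch_norm",384,768
"mixed10_3x3_2b","conv",442368,0
"mixed10_3x3_2b_bn","batch_norm",384,768
"mixed10_dbl_1","conv",917504,0
"mixed10_dbl_1_bn","batch_norm",448,896
"mixed10_dbl_2","conv",1548288,0
"mixed10_dbl_2_bn","batch_norm",384,768
"mixed10_dbl_3a","conv",442368,0
"mixed10_dbl_3a_bn","batch_norm",384,768
"mixed10_dbl_3b","conv",442368,0
"mixed10_dbl_3b_bn","batch_norm",384,768
"mixed10_pool","conv",393216,0
"mixed10_pool_bn","batch_norm",192,384
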
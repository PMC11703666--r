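conv2d0_pre_relu
conv2d0
maxpool0
localresponsenorm0
conv2d1_pre_relu
conv2d1
conv2d2_pre_relu
conv2d2
localresponsenorm1
maxpool1
mixed3a_1x1_pre_relu
mixed3a_1x1
mixed3a_3x3_bottleneck_pre_relu
mixed3a_3x3_bottleneck
mixed3a_3x3_pre_relu
mixed3a_3x3
mixed3a_5x5_bottleneck_pre_relu
mixed3a_5x5_bottleneck
mixed3a_5x5_pre_relu
mixed3a_5x5
mixed3a_pool
mixed3a_pool_reduce_pre_relu
mixed3a_pool_reduce
mixed3a
mixed3b_1x1_pre_relu
mixed3b_1x1
mixed3b_3x3_bottleneck_pre_relu
mixed3b_3x3_bottleneck
mixed3b_3x3_pre_relu
mixed3b_3x3
mixed3b_5x5_bottleneck_pre_relu
mixed3b_5x5_bottleneck
mixed3b_5x5_pre_relu
mixed3b_5x5
mixed3b_pool
mixed3b_pool_reduce_pre_relu
mixed3b_pool_reduce
mixed3b
maxpool4
mixed4a_1x1_pre_relu
mixed4a_1x1
mixed4a_3x3_bottleneck_pre_relu
mixed4a_3x3_bottleneck
mixed4a_3x3_pre_relu
mixed4a_3x3
mixed4a_5x5_bottleneck_pre_relu
mixed4a_5x5_bottleneck
mixed4a_5x5_pre_relu
mixed4a_5x5
mixed4a_pool
mixed4a_pool_reduce_pre_relu
mixed4a_pool_reduce
mixed4a
mixed4b_1x1_pre_relu
mixed4b_1x1
mixed4b_3x3_bottleneck_pre_relu
mixed4b_3x3_bottleneck
mixed4b_3x3_pre_relu
mixed4b_3x3
mixed4b_5x5_bottleneck_pre_relu
mixed4b_5x5_bottleneck
mixed4b_5x5_pre_relu
mixed4b_5x5
mixed4b_pool
mixed4b_pool_reduce_pre_relu
mixed4b_pool_reduce
mixed4b
mixed4c_1x1_pre_relu
mixed4c_1x1
mixed4c_3x3_bottleneck_pre_relu
mixed4c_3x3_bottleneck
mixed4c_3x3_pre_relu
mixed4c_3x3
mixed4c_5x5_bottleneck_pre_relu
mixed4c_5x5_bottleneck
mixed4c_5x5_pre_relu
mixed4c_5x5
mixed4c_pool
mixed4c_pool_reduce_pre_relu
mixed4c_pool_reduce
mixed4c
mixed4d_1x1_pre_relu
mixed4d_1x1
mixed4d_3x3_bottleneck_pre_relu
mixed4d_3x3_bottleneck
mixed4d_3x3_pre_relu
mixed4d_3x3
mixed4d_5x5_bottleneck_pre_relu
mixed4d_5x5_bottleneck
mixed4d_5x5_pre_relu
mixed4d_5x5
mixed4d_pool
mixed4d_pool_reduce_pre_relu
mixed4d_pool_reduce
mixed4d
mixed4e_1x1_pre_relu
mixed4e_1x1
mixed4e_3x3_bottleneck_pre_relu
mixed4e_3x3_bottleneck
mixed4e_3x3_pre_relu
mixed4e_3x3
mixed4e_5x5_bottleneck_pre_relu
mixed4e_5x5_bottleneck
mixed4e_5x5_pre_relu
mixed4e_5x5
mixed4e_pool
mixed4e_pool_reduce_pre_relu
mixed4e_pool_reduce
mixed4e
maxpool10
mixed5a_1x1_pre_relu
mixed5a_1x1
mixed5a_3x3_bottleneck_pre_relu
mixed5a_3x3_bottleneck
mixed5a_3x3_pre_relu
mixed5a_3x3
mixed5a_5x5_bottleneck_pre_relu
mixed5a_5x5_bottleneck
mixed5a_5x5_pre_relu
mixed5a_5x5
mixed5a_pool
mixed5a_pool_reduce_pre_relu
mixed5a_pool_reduce
mixed5a
mixed5b_1x1_pre_relu
mixed5b_1x1
mixed5b_3x3_bottleneck_pre_relu
mixed5b_3x3_bottleneck
mixed5b_3x3_pre_relu
mixed5b_3x3
mixed5b_5x5_bottleneck_pre_relu
mixed5b_5x5_bottleneck
mixed5b_5x5_pre_relu
mixed5b_5x5
mixed5b_pool
mixed5b_pool_reduce_pre_relu
mixed5b_pool_reduce
mixed5b
avgpool0
nn0_pre_relu
nn0
nn1_pre_relu
nn1
output
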
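arch,dropout,d,batch,task,micro,macro
MT,0.0,2,64,site,0.9292,0.6553
MT,0.0,2,64,subsite,0.6552,0.2869
MT,0.0,2,64,laterality,0.9149,0.5162
MT,0.0,2,64,histology,0.7781,0.2913
MT,0.0,2,64,behavior,0.9730,0.8873
MT,0.0,2,64,grade,0.7642,0.6197
MT,0.0,2,256,site,0.9260,0.6727
MT,0.0,2,256,subsite,0.6444,0.3008
MT,0.0,2,256,laterality,0.9096,0.5149
MT,0.0,2,256,histology,0.7752,0.3219
MT,0.0,2,256,behavior,0.9726,0.8907
MT,0.0,2,256,grade,0.7467,0.6411
MT,0.0,5,64,site,0.9298,0.6762
MT,0.0,5,64,subsite,0.6521,0.3072
MT,0.0,5,64,laterality,0.9145,0.5159
MT,0.0,5,64,histology,0.7782,0.3197
MT,0.0,5,64,behavior,0.9731,0.8899
MT,0.0,5,64,grade,0.7624,0.6538
MT,0.0,5,256,site,0.9267,0.6747
MT,0.0,5,256,subsite,0.6424,0.3069
MT,0.0,5,256,laterality,0.9098,0.5141
MT,0.0,5,256,histology,0.7783,0.3240
MT,0.0,5,256,behavior,0.9735,0.8909
MT,0.0,5,256,grade,0.7536,0.6556
MT,0.0,10,64,site,0.9277,0.6704
MT,0.0,10,64,subsite,0.6528,0.2981
MT,0.0,10,64,laterality,0.9156,0.5173
MT,0.0,10,64,histology,0.7788,0.3137
MT,0.0,10,64,behavior,0.9728,0.8778
MT,0.0,10,64,grade,0.7654,0.6677
MT,0.0,10,256,site,0.9279,0.6696
MT,0.0,10,256,subsite,0.6464,0.3097
MT,0.0,10,256,laterality,0.9113,0.5254
MT,0.0,10,256,histology,0.7765,0.3363
MT,0.0,10,256,behavior,0.9720,0.8547
MT,0.0,10,256,grade,0.7541,0.6380
MT,0.25,2,256,site,0.9306,0.6738
MT,0.25,2,256,subsite,0.6548,0.3073
MT,0.25,2,256,laterality,0.9147,0.5136
MT,0.25,2,256,histology,0.7798,0.2949
MT,0.25,2,256,behavior,0.9737,0.8758
MT,0.25,2,256,grade,0.7649,0.6726
MT,0.25,5,256,site,0.9307,0.6834
MT,0.25,5,256,subsite,0.6534,0.2967
MT,0.25,5,256,laterality,0.9145,0.5081
MT,0.25,5,256,histology,0.7792,0.3073
MT,0.25,5,256,behavior,0.9739,0.8932
MT,0.25,5,256,grade,0.7630,0.6608
MT,0.25,10,256,site,0.9306,0.6768
MT,0.25,10,256,subsite,0.6548,0.3049
MT,0.25,10,256,laterality,0.9150,0.5204
MT,0.25,10,256,histology,0.7802,0.3391
MT,0.25,10,256,behavior,0.9739,0.8925
MT,0.25,10,256,grade,0.7627,0.6653
ST,0.25,10,256,site,0.9310,0.6571
ST,0.25,10,256,subsite,0.6532,0.3045
ST,0.25,10,256,laterality,0.9143,0.5085
ST,0.25,10,256,histology,0.7785,0.3183
ST,0.25,10,256,behavior,0.9739,0.8797
ST,0.25,10,256,grade,0.7567,0.6600
MT-CNN,0.25,NA,256,site,0.9250,0.6754
MT-CNN,0.25,NA,256,subsite,0.6538,0.3208
MT-CNN,0.25,NA,256,laterality,0.9000,0.5083
MT-CNN,0.25,NA,256,histology,0.7651,0.3642
MT-CNN,0.25,NA,256,behavior,0.9652,0.8700
MT-CNN,0.25,NA,256,grade,0.7401,0.6345
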
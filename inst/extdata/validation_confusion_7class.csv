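classifier,mouth_nose,right_eye,left_eye,right_ear,left_ear,low_risk,occlusion
mouth_nose,74,7,14,0,0,1,0
right_eye,12,55,1,9,0,1,0
left_eye,7,0,64,0,5,1,0
right_ear,0,1,0,69,0,6,0
left_ear,0,1,1,0,68,6,0
low_risk,0,5,2,4,7,64,5
occlusion,0,0,0,0,0,20,65
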
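gender,age,bmi,hr,sp,dp,cc,av,tcad,lvef,lvm,stenosis_location,ds,ffr
female,47.067,35.692,86.394,93.369,99.936,FALSE,3.973,right,27.44,156.726,LAD,62.681,0.511
male,47.359,25.317,83.37,117.124,45.477,FALSE,2.536,right,63.842,176.957,LAD,66.92,0.65
male,68.552,33.649,96.884,97.139,70.415,FALSE,7.024,left,60.904,168.25,LAD,60.034,0.716
male,57.738,26.079,36.27,150.549,82.258,TRUE,1.329,right,40.332,178.089,LCX,83.264,0.794
male,61.108,18.863,96.141,130.118,105.66,FALSE,2.843,balanced,59.174,180.833,LAD,60.233,0.785
female,86.575,21.971,71.644,123.764,55.988,FALSE,3.534,right,60.772,166.496,RCA,80.493,0.859
male,63.662,23.574,84.426,112.272,66.707,FALSE,3.62,right,68.193,159.635,LAD,93.47,0.578
female,93.159,28.837,80.814,107.513,40.131,FALSE,2.773,right,71.303,124.941,LCX,86.185,0.985
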
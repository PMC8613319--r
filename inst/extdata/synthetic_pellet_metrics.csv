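pellet_id,config,reconstruction,omar,mean_hu,noise,snr,cnr
R1,unilateral,conventional,off,132.2,34.6,3.82,6.45
R1,unilateral,conventional,on,177.2,14.6,12.14,16.88
R1,unilateral,vmi130,off,143.6,13.7,10.48,13.61
R1,unilateral,vmi130,on,145.1,10.1,14.37,16.58
R2,unilateral,conventional,off,190.5,39.6,4.81,8.28
R2,unilateral,conventional,on,224.8,18.9,11.89,17.77
R2,unilateral,vmi130,off,147.1,14,10.51,13.75
R2,unilateral,vmi130,on,147.3,10.5,14.03,16.46
R3,unilateral,conventional,off,140.9,36.7,3.84,6.54
R3,unilateral,conventional,on,174.5,16.1,10.84,15.51
R3,unilateral,vmi130,off,147.3,15.2,9.69,13.04
R3,unilateral,vmi130,on,146.6,10.3,14.23,16.56
R4,unilateral,conventional,off,151.6,37.8,4.01,6.86
R4,unilateral,conventional,on,182.5,18.5,9.86,14.66
R4,unilateral,vmi130,off,143,14.9,9.6,12.83
R4,unilateral,vmi130,on,148.3,12.5,11.86,14.9
R5,unilateral,conventional,off,251.9,7.1,35.48,37.32
R5,unilateral,conventional,on,252.4,8.2,30.78,34.58
R5,unilateral,vmi130,off,147.2,8.2,17.95,18.87
R5,unilateral,vmi130,on,146.7,9.1,16.12,17.78
R6,unilateral,conventional,off,242.1,7.1,34.1,35.87
R6,unilateral,conventional,on,243.6,7.3,33.37,35.56
R6,unilateral,vmi130,off,149.7,9,16.63,18.26
R6,unilateral,vmi130,on,144.1,9.3,15.49,17.26
R7,unilateral,conventional,off,195.4,17.9,10.92,16.08
R7,unilateral,conventional,on,225.9,10.6,21.31,26.58
R7,unilateral,vmi130,off,148.5,9.2,16.14,17.89
R7,unilateral,vmi130,on,149.2,9.3,16.04,17.87
R8,unilateral,conventional,off,75.9,38.4,1.98,3.39
R8,unilateral,conventional,on,175.6,16.1,10.91,15.61
R8,unilateral,vmi130,off,142.1,12.5,11.37,14.28
R8,unilateral,vmi130,on,142.2,12.7,11.2,14.15
R9,unilateral,conventional,off,147.4,25.2,5.85,9.33
R9,unilateral,conventional,on,178.9,13,13.76,18.44
R9,unilateral,vmi130,off,146.2,10.4,14.06,16.43
R9,unilateral,vmi130,on,144.4,10.4,13.88,16.22
L1,unilateral,conventional,off,246.9,7.6,32.49,35.27
L1,unilateral,conventional,on,252.4,7.6,33.21,36.06
L1,unilateral,vmi130,off,150.9,8.6,17.55,18.86
L1,unilateral,vmi130,on,148.5,10,14.85,17.07
L2,unilateral,conventional,off,247.1,7.3,33.85,36.07
L2,unilateral,conventional,on,245.1,7.1,34.52,36.31
L2,unilateral,vmi130,off,151.3,8.2,18.45,19.4
L2,unilateral,vmi130,on,145.4,9.4,15.47,17.31
L3,unilateral,conventional,off,247,7.1,34.79,36.59
L3,unilateral,conventional,on,249.2,7.6,32.79,35.6
L3,unilateral,vmi130,off,150.7,8.9,16.93,18.49
L3,unilateral,vmi130,on,151.7,9.5,15.97,17.95
L4,unilateral,conventional,off,246.2,7.8,31.56,34.68
L4,unilateral,conventional,on,247,7,35.29,36.87
L4,unilateral,vmi130,off,145.8,9.3,15.68,17.46
L4,unilateral,vmi130,on,146.9,8.2,17.91,18.83
L5,unilateral,conventional,off,244,8.1,30.12,33.66
L5,unilateral,conventional,on,250.9,7.3,34.37,36.63
L5,unilateral,vmi130,off,149,8.6,17.33,18.62
L5,unilateral,vmi130,on,143.5,8.6,16.69,17.94
L6,unilateral,conventional,off,246.6,8,30.82,34.25
L6,unilateral,conventional,on,249.6,8.3,30.07,33.96
L6,unilateral,vmi130,off,147,8.4,17.5,18.61
L6,unilateral,vmi130,on,152.4,8.3,18.36,19.41
L7,unilateral,conventional,off,246.8,7.6,32.47,35.26
L7,unilateral,conventional,on,248,7.1,34.93,36.74
L7,unilateral,vmi130,off,148.1,8.8,16.83,18.28
L7,unilateral,vmi130,on,148.5,9.9,15,17.17
L8,unilateral,conventional,off,246.2,7.4,33.27,35.68
L8,unilateral,conventional,on,247.6,7.4,33.46,35.88
L8,unilateral,vmi130,off,146.4,8,18.3,19.01
L8,unilateral,vmi130,on,149.6,10.4,14.38,16.81
L9,unilateral,conventional,off,245.3,7.5,32.71,35.29
L9,unilateral,conventional,on,249.5,7.1,35.14,36.96
L9,unilateral,vmi130,off,146.2,8.2,17.83,18.74
L9,unilateral,vmi130,on,144.2,9.5,15.18,17.07
R1,bilateral,conventional,off,169,15.9,10.63,15.16
R1,bilateral,conventional,on,194.7,9.3,20.94,24.8
R1,bilateral,vmi130,off,146.3,9.7,15.08,17.11
R1,bilateral,vmi130,on,148.7,9.2,16.16,17.92
R2,bilateral,conventional,off,183.9,28.5,6.45,10.54
R2,bilateral,conventional,on,215.3,11.6,18.56,23.92
R2,bilateral,vmi130,off,148.9,12.3,12.11,15.12
R2,bilateral,vmi130,on,149.1,10.4,14.34,16.75
R3,bilateral,conventional,off,-42.5,75.5,-0.56,-1.04
R3,bilateral,conventional,on,174.8,14.1,12.4,17.05
R3,bilateral,vmi130,off,-457.7,161.8,-2.83,-5.41
R3,bilateral,vmi130,on,128,16.9,7.57,10.53
R4,bilateral,conventional,off,-83.4,84.3,-0.99,-1.84
R4,bilateral,conventional,on,149.2,19.6,7.61,11.48
R4,bilateral,vmi130,off,-421.1,193.7,-2.17,-4.19
R4,bilateral,vmi130,on,123.1,20.6,5.98,8.79
R5,bilateral,conventional,off,152.5,21.7,7.03,10.85
R5,bilateral,conventional,on,209.5,11.1,18.87,23.94
R5,bilateral,vmi130,off,144.5,10.2,14.17,16.42
R5,bilateral,vmi130,on,147.2,8.9,16.54,18.06
R6,bilateral,conventional,off,248.1,7.3,33.99,36.22
R6,bilateral,conventional,on,248.2,7.2,34.47,36.5
R6,bilateral,vmi130,off,147.4,8.7,16.94,18.31
R6,bilateral,vmi130,on,142,8.9,15.96,17.42
R7,bilateral,conventional,off,-131.8,70.4,-1.87,-3.43
R7,bilateral,conventional,on,185.7,18.4,10.09,14.98
R7,bilateral,vmi130,off,-514.8,161.9,-3.18,-6.08
R7,bilateral,vmi130,on,120.7,15.7,7.69,10.45
R8,bilateral,conventional,off,-186.7,99.8,-1.87,-3.52
R8,bilateral,conventional,on,122.4,25.8,4.74,7.6
R8,bilateral,vmi130,off,-548,231.6,-2.37,-4.59
R8,bilateral,vmi130,on,122.6,16.8,7.3,10.13
R9,bilateral,conventional,off,76.8,24.2,3.17,5.02
R9,bilateral,conventional,on,139.6,12.4,11.26,14.85
R9,bilateral,vmi130,off,145.1,11.3,12.84,15.52
R9,bilateral,vmi130,on,145.3,10.6,13.71,16.14
L1,bilateral,conventional,off,102.9,23,4.47,7
L1,bilateral,conventional,on,156.3,11.8,13.25,17.18
L1,bilateral,vmi130,off,146.3,10.1,14.49,16.72
L1,bilateral,vmi130,on,145.5,9.5,15.32,17.22
L2,bilateral,conventional,off,187.4,30.9,6.06,10.05
L2,bilateral,conventional,on,212.3,13.1,16.21,21.77
L2,bilateral,vmi130,off,147.1,11,13.37,15.99
L2,bilateral,vmi130,on,147.2,10.7,13.76,16.27
L3,bilateral,conventional,off,-217.2,101,-2.15,-4.04
L3,bilateral,conventional,on,162.2,17,9.54,13.86
L3,bilateral,vmi130,off,-518.1,310.4,-1.67,-3.26
L3,bilateral,vmi130,on,104.5,16.1,6.49,8.89
L4,bilateral,conventional,off,-41.1,107.6,-0.38,-0.72
L4,bilateral,conventional,on,162.4,20.1,8.08,12.26
L4,bilateral,vmi130,off,-438.6,342.3,-1.28,-2.51
L4,bilateral,vmi130,on,130.7,16.6,7.87,10.89
L5,bilateral,conventional,off,110,31.9,3.45,5.74
L5,bilateral,conventional,on,159.7,13.6,11.74,15.97
L5,bilateral,vmi130,off,146.2,11.8,12.39,15.23
L5,bilateral,vmi130,on,143.1,11.5,12.44,15.14
L6,bilateral,conventional,off,248.1,8.2,30.26,33.99
L6,bilateral,conventional,on,246.6,7.2,34.25,36.26
L6,bilateral,vmi130,off,147,9,16.33,17.93
L6,bilateral,vmi130,on,150.8,8.9,16.94,18.5
L7,bilateral,conventional,off,-105.5,99.8,-1.06,-1.99
L7,bilateral,conventional,on,174.1,26.5,6.57,10.58
L7,bilateral,vmi130,off,-608.7,285.3,-2.13,-4.16
L7,bilateral,vmi130,on,123.7,25.2,4.91,7.59
L8,bilateral,conventional,off,-149.3,56.2,-2.66,-4.77
L8,bilateral,conventional,on,155.4,12.1,12.84,16.8
L8,bilateral,vmi130,off,-443.3,167.4,-2.65,-5.07
L8,bilateral,vmi130,on,121.7,14.6,8.34,11.06
L9,bilateral,conventional,off,202.2,33.8,5.98,10.06
L9,bilateral,conventional,on,225.9,15.5,14.57,20.63
L9,bilateral,vmi130,off,147.7,11.4,12.96,15.71
L9,bilateral,vmi130,on,149.4,10.7,13.96,16.51
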
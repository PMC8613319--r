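label,x_mm,y_mm,diameter_mm
R1,127,102,10
R2,45,60,10
R3,105,60,10
R4,120,-20,10
R5,120,-60,10
R6,120,-100,10
R7,45,-100,10
R8,55,-20,10
R9,55,20,10
L1,-127,102,10
L2,-45,60,10
L3,-105,60,10
L4,-120,-20,10
L5,-120,-60,10
L6,-120,-100,10
L7,-45,-100,10
L8,-55,-20,10
L9,-55,20,10
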
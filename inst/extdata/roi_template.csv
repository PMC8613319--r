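label,x_mm,y_mm,diameter_mm,diameter_px
R1,127,102,6.75,15
R2,45,60,6.75,15
R3,105,60,6.75,15
R4,120,-20,6.75,15
R5,120,-60,6.75,15
R6,120,-100,6.75,15
R7,45,-100,6.75,15
R8,55,-20,6.75,15
R9,55,20,6.75,15
L1,-127,102,6.75,15
L2,-45,60,6.75,15
L3,-105,60,6.75,15
L4,-120,-20,6.75,15
L5,-120,-60,6.75,15
L6,-120,-100,6.75,15
L7,-45,-100,6.75,15
L8,-55,-20,6.75,15
L9,-55,20,6.75,15
BG,0,-125,6.75,15
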
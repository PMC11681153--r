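row,C1,C2,C3,C4,C5,C6
C1,0.000,0.712,0.742,0.430,0.595,0.430
C2,0.554,0.000,0.554,0.582,0.601,0.430
C3,0.742,0.976,0.000,0.881,0.449,0.582
C4,0.742,0.712,0.831,0.000,0.601,0.881
C5,0.831,0.712,0.742,0.582,0.000,0.430
C6,0.742,0.712,0.554,0.430,0.595,0.000
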
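criterion,C1,C2,C3,C4,C5,C6
C1,-,K4,K6,K4,K8,K4
C2,K5,-,K5,K5,K6,K4
C3,K6,K5,-,K7,K5,K5
C4,K6,K4,K7,-,K6,K7
C5,K7,K4,K6,K5,-,K4
C6,K6,K4,K5,K4,K8,-
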
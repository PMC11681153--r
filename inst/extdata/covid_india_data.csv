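alternative,C1,C2,C3,C4,C5,C6
d1,32433,25500,2795,2062,97,77
d2,663464,566640,53118,44665,272,153
d3,1859655,1493623,141900,106762,595,505
d4,4863748,3424344,381877,247425,3562,2189
d5,5574392,3392564,484538,267434,12324,4833
d6,4220769,2750252,387151,226250,24083,11251
d7,3323505,2327632,311917,197033,39339,20921
d8,2191686,1607215,211645,150805,50661,28396
d9,1049700,714205,103857,67464,39533,19875
d10,302475,218457,27561,18059,16409,7792
d11,41778,39051,3638,3405,2509,1533
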
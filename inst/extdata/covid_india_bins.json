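[{"lower":0,"upper":1000,"code":"K0"},{"lower":1001,"upper":25000,"code":"K1"},{"lower":25001,"upper":100000,"code":"K2"},{"lower":100001,"upper":250000,"code":"K3"},{"lower":250001,"upper":500000,"code":"K4"},{"lower":500001,"upper":1000000,"code":"K5"},{"lower":1000001,"upper":2000000,"code":"K6"},{"lower":2000001,"upper":3000000,"code":"K7"},{"lower":3000001,"upper":4000000,"code":"K8"},{"lower":4000001,"upper":5000000,"code":"K9"},{"lower":5000001,"upper":"Inf","code":"K10"}]
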
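{"source":"eleven-term TSFN assessment scale, stored as published","terms":[
{"code":"K0","label":"Ultra low","value":{"a":0,"b":0.05,"c":0.1,"mu":0.95,"eta":0.05,"nu":0.1}},
{"code":"K1","label":"Supreme low","value":{"a":0.07,"b":0.14,"c":0.21,"mu":0.05,"eta":0.1,"nu":0.2}},
{"code":"K2","label":"Very low","value":{"a":0.18,"b":0.22,"c":0.26,"mu":0.85,"eta":0.2,"nu":0.25}},
{"code":"K3","label":"Slightly low","value":{"a":0.25,"b":0.28,"c":0.3,"mu":0.8,"eta":0.3,"nu":0.3}},
{"code":"K4","label":"Low","value":{"a":0.29,"b":0.36,"c":0.43,"mu":0.7,"eta":0.35,"nu":0.4}},
{"code":"K5","label":"Intermediate","value":{"a":0.38,"b":0.45,"c":0.52,"mu":0.65,"eta":0.4,"nu":0.5}},
{"code":"K6","label":"High","value":{"a":0.5,"b":0.56,"c":0.62,"mu":0.55,"eta":0.5,"nu":0.6}},
{"code":"K7","label":"Slightly high","value":{"a":0.61,"b":0.68,"c":0.75,"mu":0.45,"eta":0.4,"nu":0.7}},
{"code":"K8","label":"Very high","value":{"a":0.73,"b":0.83,"c":0.88,"mu":0.25,"eta":0.2,"nu":0.75}},
{"code":"K9","label":"Supreme high","value":{"a":0.85,"b":0.94,"c":0.98,"mu":0.1,"eta":0.1,"nu":0.85}},
{"code":"K10","label":"Ultra high","value":{"a":0.95,"b":0.985,"c":1,"mu":0.05,"eta":0.05,"nu":0.95}}]}
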
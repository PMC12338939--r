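partition,source,BEK,NEV,ACK,BCC,MEL
training,BCN20000,796,2944,515,1966,1999
training,Derm12345,430,1683,16,291,263
training,DDI,22,22,0,7,5
training,Derm7pt,46,18,0,26,160
training,DermNet,171,39,38,133,62
validation,BCN20000,170,630,110,421,428
validation,Derm12345,110,455,13,47,55
validation,Derm7pt,21,8,0,12,69
validation,DermNet,25,7,6,19,10
testing,BCN20000,172,632,112,422,430
testing,Derm12345,135,534,8,85,82
testing,Derm7pt,13,5,0,7,45
testing,DermNet,49,11,11,38,18
testing,HAM10000,1338,7737,378,622,1305
testing,SKINL2,33,97,0,40,28
testing,Fitzpatrick17k,30,39,5,36,115
testing,BuenosAires,88,602,63,340,253
testing,SD198,60,32,62,13,38
testing,PADUFES20,52,68,13,64,26
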
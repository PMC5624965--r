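time,speed_in,speed_out
7.395353135259,0.499940095463,0.399952076371
8.238984485776,0.381841736342,0.305473389074
9.058530404240,0.212274019788,0.169819215830
15.401864964095,2.142832556326,1.714266045061
21.560610733363,2.958495331932,2.366796265546
27.765162735443,3.250544373392,2.600435498713
34.005666322392,3.330014055667,2.664011244533
40.269056731370,3.337401728500,2.669921382800
46.544615598869,3.328186363180,2.662549090544
52.825554751036,3.319658401833,2.655726721467
59.108415095729,3.314784614680,2.651827691744
66.140315850180,1.967925570203,1.574340456162
72.341892831754,0.811071684862,0.648857347890
79.120053748234,0.285506252912,0.228405002330
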
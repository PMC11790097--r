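t,psi
0.00390625,-5.83988029548e-06
0.25390625,-0.00505090327647
0.50390625,-0.0153000719514
0.75390625,-0.0286360758148
1.00390625,-0.0465960583894
1.25390625,-0.0220064138479
1.50390625,0.0463601763493
1.75390625,0.137353182269
2.00390625,0.265314991581
2.25390625,0.203807486049
2.50390625,-0.0522203325762
2.75390625,-0.395919079218
3.00390625,-0.895049191018
3.25390625,-0.413880237404
3.50390625,1.07336390077
3.75390625,0.97391358319
4.00390625,-0.429215452588
4.25390625,-0.545282669743
4.50390625,0.0773381707804
4.75390625,0.102801904496
5.00390625,-0.0270606481112
5.25390625,-0.00603323818715
5.50390625,0.00254709575471
5.75390625,-0.0010280381447
6.00390625,0.000532662190086
6.25390625,-3.96744195983e-05
6.50390625,-9.40290933294e-06
6.75390625,1.74051490337e-07
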
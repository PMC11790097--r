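t,psi
0.00390625,0
0.25390625,0
0.50390625,0
0.75390625,0
1.00390625,-1.59125193022e-08
1.25390625,0.00089663608378
1.50390625,0.0160350059523
1.75390625,-0.12877784887
2.00390625,0.163653728465
2.25390625,0.70505009513
2.50390625,-1.377949374
2.75390625,-1.80436793758
3.00390625,3.48174237546
3.25390625,2.38280380673
3.50390625,-4.22163611274
3.75390625,-1.38061596263
4.00390625,2.75226868343
4.25390625,-0.00872668900411
4.50390625,-0.960880410013
4.75390625,0.314805710834
5.00390625,0.136627583743
5.25390625,-0.0819765120032
5.50390625,0.0101385356174
5.75390625,0.000908701309527
6.00390625,0
6.25390625,0
6.50390625,0
6.75390625,0
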
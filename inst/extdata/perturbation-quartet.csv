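# walkstab fixture: perturbation-quartet (deviation-from-orbit series, +1 cm perturbation at t = 1 s)
system,b_p,b_d,n,t_mid,dev
1,2.5,0.3,0,0,0
1,2.5,0.3,1,0.5,1.00074151062e-16
1,2.5,0.3,2,1,0.01
1,2.5,0.3,3,1.5,0.00898564863048
1,2.5,0.3,4,2,0.00856380614486
1,2.5,0.3,5,2.5,0.0102411978701
1,2.5,0.3,6,3,0.0146715497995
1,2.5,0.3,7,3.5,0.0244016409377
1,2.5,0.3,8,4,0.0414838647225
1,2.5,0.3,9,4.5,0.0719463729136
1,2.5,0.3,10,5,0.124524878064
1,2.5,0.3,11,5.5,0.21617629815
1,2.5,0.3,12,6,0.374908733833
1,2.5,0.3,13,6.5,0.650595575526
1,2.5,0.3,14,7,1.12869500476
1,2.5,0.3,15,7.5,1.9584154495
1,2.5,0.3,16,8,3.39783839377
1,2.5,0.3,17,8.5,5.89543491182
1,2.5,0.3,18,9,10.2287241881
1,2.5,0.3,19,9.5,17.7472400815
1,2.5,0.3,20,10,30.792030617
2,2.5,0.6,0,0,0
2,2.5,0.6,1,0.5,1.00074151062e-16
2,2.5,0.6,2,1,0.01
2,2.5,0.6,3,1.5,0.00898564863048
2,2.5,0.6,4,2,0.00631080110704
2,2.5,0.6,5,2.5,0.0057752956111
2,2.5,0.6,6,3,0.0039896251994
2,2.5,0.6,7,3.5,0.00372566854375
2,2.5,0.6,8,4,0.00252898454699
2,2.5,0.6,9,4.5,0.00241406850327
2,2.5,0.6,10,5,0.00160941273914
2,2.5,0.6,11,5.5,0.0015723633782
2,2.5,0.6,12,6,0.00102989081306
2,2.5,0.6,13,6.5,0.00103033234116
2,2.5,0.6,14,7,0.000663993210581
2,2.5,0.6,15,7.5,0.000679809798533
2,2.5,0.6,16,8,0.000432255128246
2,2.5,0.6,17,8.5,0.00045198429675
2,2.5,0.6,18,9,0.000284767897378
2,2.5,0.6,19,9.5,0.000303019517567
2,2.5,0.6,20,10,0.000190220240253
3,2.5,1.1,0,0,0
3,2.5,1.1,1,0.5,1.00074151062e-16
3,2.5,1.1,2,1,0.01
3,2.5,1.1,3,1.5,0.00898564863048
3,2.5,1.1,4,2,0.00626728147253
3,2.5,1.1,5,2.5,0.00393310559045
3,2.5,1.1,6,3,0.00369631009298
3,2.5,1.1,7,3.5,0.00389665999968
3,2.5,1.1,8,4,0.00326608357187
3,2.5,1.1,9,4.5,0.00214677287318
3,2.5,1.1,10,5,0.00143726726019
3,2.5,1.1,11,5.5,0.00148838589961
3,2.5,1.1,12,6,0.00149090836167
3,2.5,1.1,13,6.5,0.00116501402463
3,2.5,1.1,14,7,0.000732693498898
3,2.5,1.1,15,7.5,0.000549530511544
3,2.5,1.1,16,8,0.000594920478838
3,2.5,1.1,17,8.5,0.000559692065867
3,2.5,1.1,18,9,0.00040825047741
3,2.5,1.1,19,9.5,0.000252723223841
3,2.5,1.1,20,10,0.00021746438245
4,2.5,1.5,0,0,0
4,2.5,1.5,1,0.5,1.00074151062e-16
4,2.5,1.5,2,1,0.01
4,2.5,1.5,3,1.5,0.00898564863048
4,2.5,1.5,4,2,0.00941366536587
4,2.5,1.5,5,2.5,0.0182938398167
4,2.5,1.5,6,3,0.0336393893821
4,2.5,1.5,7,3.5,0.0508999154402
4,2.5,1.5,8,4,0.0644642046906
4,2.5,1.5,9,4.5,0.0678152197186
4,2.5,1.5,10,5,0.0595955500322
4,2.5,1.5,11,5.5,0.0702151454395
4,2.5,1.5,12,6,0.140741264483
4,2.5,1.5,13,6.5,0.24997219124
4,2.5,1.5,14,7,0.366352190025
4,2.5,1.5,15,7.5,0.449803523085
4,2.5,1.5,16,8,0.457019233581
4,2.5,1.5,17,8.5,0.397791573816
4,2.5,1.5,18,9,0.534313884608
4,2.5,1.5,19,9.5,1.07676782675
4,2.5,1.5,20,10,1.84663750456
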
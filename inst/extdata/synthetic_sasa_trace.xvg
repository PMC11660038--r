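@ observable sasa
@ xaxis label "Time (ns)"
0 694.4981878
0.02 692.5367675
0.04 676.5956484
0.06 676.2507371
0.08 657.9250497
0.1 662.9467331
0.12 662.7549416
0.14 658.9065524
0.16 638.1874346
0.18 637.1362891
0.2 628.1531387
0.22 629.0161569
0.24 624.5184082
0.26 634.8701685
0.28 612.5864298
0.3 604.345801
0.32 608.2388694
0.34 602.0171916
0.36 595.96839
0.38 598.2360476
0.4 595.343192
0.42 587.8775731
0.44 581.5255164
0.46 571.1422655
0.48 569.7171513
0.5 577.8298996
0.52 567.7926
0.54 574.6558313
0.56 570.6407929
0.58 563.4551178
0.6 554.4832348
0.62 561.7618289
0.64 558.904111
0.66 555.8348341
0.68 551.2728749
0.7 545.8482072
0.72 549.2532422
0.74 552.4618108
0.76 532.07875
0.78 543.4364603
0.8 542.0917114
0.82 544.4231033
0.84 537.9739358
0.86 533.2840936
0.88 535.4877762
0.9 532.7972698
0.92 537.4733139
0.94 530.9527023
0.96 524.0313715
0.98 530.7276476
1 526.2569923
1.02 519.0241726
1.04 529.8817778
1.06 525.453096
1.08 527.5290035
1.1 519.7244694
1.12 518.9383998
1.14 522.0568897
1.16 528.6846698
1.18 518.1434659
1.2 528.4772332
1.22 522.6950877
1.24 519.5596968
1.26 508.9365605
1.28 513.0281857
1.3 517.2502154
1.32 514.8731997
1.34 513.5389271
1.36 508.391775
1.38 509.5974509
1.4 505.9075752
1.42 509.4101307
1.44 505.8452265
1.46 515.3649055
1.48 510.0699847
1.5 504.7565762
1.52 514.0595516
1.54 513.8864652
1.56 503.9917095
1.58 508.6754829
1.6 517.1047849
1.62 515.5668715
1.64 511.7000944
1.66 515.9938559
1.68 499.9156831
1.7 509.8832222
1.72 503.9120744
1.74 499.1372852
1.76 506.7752973
1.78 505.876908
1.8 508.7757046
1.82 501.6400273
1.84 511.8083718
1.86 498.1508171
1.88 502.1822474
1.9 499.6702441
1.92 497.5954219
1.94 512.7952291
1.96 496.3190727
1.98 499.9087329
2 508.2445362
2.02 507.9802576
2.04 501.5023232
2.06 495.5605308
2.08 507.0414524
2.1 510.1957858
2.12 502.9046625
2.14 499.9338413
2.16 498.7818607
2.18 512.959906
2.2 504.1731766
2.22 509.4919126
2.24 506.6409235
2.26 500.1548014
2.28 500.8740939
2.3 504.985717
2.32 510.9390179
2.34 502.5031584
2.36 503.1021983
2.38 508.8359926
2.4 496.6171932
2.42 501.0645258
2.44 503.6298053
2.46 504.5975864
2.48 499.0280486
2.5 496.1261072
2.52 505.545325
2.54 503.8450729
2.56 496.8833822
2.58 500.0991037
2.6 509.339953
2.62 498.7180555
2.64 498.8434436
2.66 493.6855181
2.68 508.1545338
2.7 499.1435533
2.72 508.0835852
2.74 509.4294754
2.76 498.7030987
2.78 502.5044732
2.8 506.8064272
2.82 496.282733
2.84 500.8653725
2.86 500.4397907
2.88 504.3082832
2.9 493.4234118
2.92 502.1563786
2.94 509.8472339
2.96 507.2690065
2.98 504.4601244
3 494.9550772
3.02 507.0726315
3.04 495.9831245
3.06 501.0510576
3.08 497.3989216
3.1 501.7905196
3.12 499.6281914
3.14 493.8787925
3.16 497.6900808
3.18 496.8525594
3.2 497.1724582
3.22 494.1877414
3.24 504.1578974
3.26 500.5464778
3.28 502.0774433
3.3 503.0075017
3.32 503.8864237
3.34 503.2899475
3.36 492.9819623
3.38 500.950479
3.4 495.8653016
3.42 499.1811287
3.44 502.0503253
3.46 499.3210956
3.48 511.1095837
3.5 502.7445611
3.52 504.2422903
3.54 498.890342
3.56 507.3095987
3.58 502.136161
3.6 496.7074599
3.62 499.1946449
3.64 496.79277
3.66 488.0003046
3.68 498.0430477
3.7 499.1301661
3.72 500.8907184
3.74 496.1039425
3.76 496.6994277
3.78 506.9772044
3.8 507.8993168
3.82 503.002591
3.84 492.3898142
3.86 500.5030913
3.88 504.3939953
3.9 493.2979935
3.92 501.239865
3.94 496.579622
3.96 494.5618719
3.98 503.2264025
4 499.0350889
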
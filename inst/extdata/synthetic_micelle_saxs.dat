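# q[A^-1]  I[cm^-1]  sigma[cm^-1]
0.005 5.107426279 0.1017810494
0.005263113246 5.168436539 0.1017714602
0.005540072209 4.950341737 0.1017608174
0.005831605485 5.289248772 0.1017490031
0.006138480015 5.212791308 0.1017358858
0.006461503096 5.208194317 0.1017213186
0.006801524507 5.176399916 0.1017051374
0.007159438746 5.110154911 0.1016871584
0.00753618738 5.139235125 0.1016671762
0.007932761525 5.275716092 0.1016449603
0.008350204452 5.227806486 0.1016202523
0.008789614332 5.091351304 0.1015927618
0.009252147124 5.014402827 0.1015621621
0.009739019617 4.947515517 0.1015280856
0.01025151263 5.051384361 0.1014901171
0.01079097438 5.045963435 0.1014477879
0.01135882404 4.910409345 0.1014005673
0.01195655546 5.245199827 0.1013478538
0.01258574108 4.894453774 0.1012889635
0.01324803612 5.114920014 0.1012231182
0.01394518288 5.133595798 0.1011494298
0.01467901535 5.032092085 0.1010668823
0.01545146402 4.915509612 0.100974311
0.01626456099 4.944525601 0.1008703768
0.01712044528 5.001721963 0.1007535366
0.01802136847 5.012458293 0.1006220066
0.01896970062 5.031961433 0.1004737191
0.01996793652 5.032716482 0.1003062706
0.02101870224 5.115175448 0.1001168586
0.02212476204 5.196127042 0.09990220556
0.02328902563 5.118859268 0.09965846714
0.02451455586 4.962700663 0.09938112035
0.02580457673 4.844313286 0.09906482825
0.02716248192 4.919835558 0.09870327567
0.02859184368 5.032299376 0.0982889698
0.03009642224 5.097718222 0.09781299847
0.03168017571 5.030289456 0.09726473812
0.03334727049 4.79657703 0.09663150208
0.03510209221 4.798020015 0.09589812012
0.03694925729 5.048328318 0.09504644037
0.0388936251 4.741055446 0.09405474818
0.04094031069 4.649342942 0.09289710262
0.0430946983 4.493814293 0.09154260412
0.0453624555 4.473249672 0.08995463008
0.04774954808 4.440154781 0.08809011371
0.0502622558 4.209234948 0.08589900431
0.05290718886 4.394219619 0.08332414393
0.0556913053 3.925114364 0.08030193478
0.05862192933 3.871451078 0.07676435813
0.06170677055 3.591063529 0.07264312165
0.06495394429 3.48844554 0.06787689684
0.06837199292 3.188759205 0.06242262017
0.07196990832 2.744279309 0.0562714144
0.07575715557 2.46920345 0.04946848779
0.07974369779 2.074753838 0.04213410513
0.08394002243 1.742339905 0.03447958894
0.08835716879 1.329431322 0.02680954701
0.09300675709 1.006030505 0.01950160889
0.09790101905 0.6404336861 0.01296042135
0.10305283 0.3779111964 0.007553310261
0.108475743 0.174886549 0.003545777054
0.1141840239 0.05230175989 0.001058082892
0.1201926898 0.002802223849 5.579276777e-05
0.1265175475 0.0192769003 0.0003720700483
0.1331752361 0.09076303628 0.001747377195
0.1401832698 0.1966403174 0.003869320564
0.1475600848 0.3187542835 0.006400787956
0.1553250874 0.4426501747 0.008993516632
0.163498705 0.565265458 0.01129316289
0.17210244 0.6548686888 0.01294969747
0.1811589264 0.6762719775 0.01365186096
0.190691989 0.6646075231 0.01319935013
0.2007267067 0.573504883 0.01159971423
0.2112894777 0.4566466852 0.009132039576
0.2224080898 0.3225032452 0.006301783903
0.2341117927 0.1910912108 0.003674444987
0.2464313755 0.0813250448 0.001679108308
0.2593992473 0.02463543163 0.0004942082828
0.2730495229 0.002306573883 4.626150689e-05
0.2874181122 0.004062879405 8.161411373e-05
0.3025428147 0.01389794761 0.0002776984927
0.3184634191 0.01838614268 0.0003811259112
0.3352218079 0.01526300063 0.0003162697727
0.3528620675 0.008442075409 0.0001697491867
0.3714306044 0.003019259162 5.937143187e-05
0.3909762668 0.001119808277 2.253594796e-05
0.4115504737 0.0009637962238 2.000324974e-05
0.4332073499 0.001175407972 2.35115188e-05
0.4560038684 0.002914395716 5.912003305e-05
0.48 0.006634145668 0.0001322941251
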
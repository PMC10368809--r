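score,time,event
3.049999999999999933e-01,1.421599999999999930e+01,1.000000000000000000e+00
-1.040000000000000036e+00,7.322499999999999432e+01,1.000000000000000000e+00
7.500000000000000000e-01,1.722200000000000131e+01,1.000000000000000000e+00
9.409999999999999476e-01,1.277999999999999936e+01,1.000000000000000000e+00
-1.951000000000000068e+00,1.963400000000000034e+01,1.000000000000000000e+00
-1.302000000000000046e+00,9.494999999999999218e+00,1.000000000000000000e+00
1.280000000000000027e-01,9.090000000000000302e-01,1.000000000000000000e+00
-3.160000000000000031e-01,1.106700000000000017e+01,1.000000000000000000e+00
-1.700000000000000122e-02,6.748000000000000220e+00,1.000000000000000000e+00
-8.529999999999999805e-01,2.012300000000000111e+01,0.000000000000000000e+00
8.790000000000000036e-01,1.596299999999999919e+01,1.000000000000000000e+00
7.780000000000000249e-01,3.025999999999999801e+00,1.000000000000000000e+00
6.600000000000000311e-02,9.779999999999999805e-01,1.000000000000000000e+00
1.127000000000000002e+00,6.951999999999999957e+00,1.000000000000000000e+00
4.680000000000000271e-01,2.262399999999999878e+01,0.000000000000000000e+00
-8.589999999999999858e-01,1.127200000000000024e+01,1.000000000000000000e+00
3.689999999999999947e-01,1.952400000000000091e+01,0.000000000000000000e+00
-9.589999999999999636e-01,1.070700000000000074e+01,1.000000000000000000e+00
8.780000000000000027e-01,1.048099999999999987e+01,1.000000000000000000e+00
-5.000000000000000278e-02,3.439000000000000057e+00,1.000000000000000000e+00
-1.849999999999999978e-01,1.949000000000000066e+00,0.000000000000000000e+00
-6.810000000000000497e-01,2.361000000000000210e+00,1.000000000000000000e+00
1.223000000000000087e+00,1.161999999999999922e+00,1.000000000000000000e+00
-1.549999999999999989e-01,1.096999999999999975e+00,1.000000000000000000e+00
-4.279999999999999916e-01,2.008599999999999852e+01,1.000000000000000000e+00
-3.519999999999999796e-01,5.541000000000000369e+00,1.000000000000000000e+00
5.320000000000000284e-01,3.717999999999999972e+00,1.000000000000000000e+00
3.649999999999999911e-01,8.827999999999999403e+00,1.000000000000000000e+00
4.129999999999999782e-01,2.096000000000000085e+00,0.000000000000000000e+00
4.309999999999999942e-01,1.729599999999999937e+01,0.000000000000000000e+00
2.141999999999999904e+00,7.057999999999999829e+00,1.000000000000000000e+00
-4.060000000000000275e-01,4.283000000000000362e+00,1.000000000000000000e+00
-5.120000000000000107e-01,2.922000000000000153e+00,1.000000000000000000e+00
-8.139999999999999458e-01,7.416999999999999815e+00,1.000000000000000000e+00
6.159999999999999920e-01,2.948999999999999844e+00,1.000000000000000000e+00
1.129000000000000004e+00,8.960000000000000187e-01,1.000000000000000000e+00
-1.140000000000000041e-01,5.729000000000000092e+00,0.000000000000000000e+00
-8.399999999999999689e-01,2.961599999999999966e+01,0.000000000000000000e+00
-8.239999999999999547e-01,1.355700000000000038e+01,1.000000000000000000e+00
6.510000000000000231e-01,2.576699999999999946e+01,0.000000000000000000e+00
7.429999999999999938e-01,1.677499999999999858e+01,1.000000000000000000e+00
5.430000000000000382e-01,9.923000000000000043e+00,1.000000000000000000e+00
-6.660000000000000364e-01,2.320899999999999963e+01,1.000000000000000000e+00
2.320000000000000118e-01,7.246999999999999886e+00,1.000000000000000000e+00
1.170000000000000068e-01,1.079199999999999982e+01,0.000000000000000000e+00
2.190000000000000002e-01,4.027999999999999581e+00,0.000000000000000000e+00
8.709999999999999964e-01,2.072000000000000064e+00,1.000000000000000000e+00
2.240000000000000047e-01,2.052199999999999847e+01,0.000000000000000000e+00
6.790000000000000480e-01,1.552000000000000046e+00,1.000000000000000000e+00
6.800000000000000488e-02,2.330999999999999961e+00,1.000000000000000000e+00
2.889999999999999791e-01,3.302999999999999936e+00,1.000000000000000000e+00
6.310000000000000053e-01,8.419999999999999929e+00,0.000000000000000000e+00
-1.457000000000000073e+00,7.181000000000000050e+00,1.000000000000000000e+00
-3.200000000000000067e-01,8.085000000000000853e+00,1.000000000000000000e+00
-4.699999999999999734e-01,2.544399999999999906e+01,1.000000000000000000e+00
-6.390000000000000124e-01,1.928000000000000114e+01,0.000000000000000000e+00
-2.750000000000000222e-01,1.326200000000000045e+01,0.000000000000000000e+00
1.495000000000000107e+00,1.411000000000000032e+00,0.000000000000000000e+00
-8.659999999999999920e-01,1.607100000000000151e+01,0.000000000000000000e+00
9.679999999999999716e-01,3.773000000000000131e+00,0.000000000000000000e+00
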
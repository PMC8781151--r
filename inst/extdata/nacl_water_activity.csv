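# Water activity of aqueous NaCl at 25 C
# a_w = exp(-2 * phi * m * M_w / 1000), M_w = 18.015 g/mol, M(NaCl) = 58.443 g/mol
# Osmotic coefficients phi: approximate values compiled from standard
# compilations (Robinson & Stokes 1959; Hamer & Wu 1972), 25 C.
# m = 0 row is the pure-water limit (phi formally 1).
molality,mass_fraction_pct,osmotic_coefficient,water_activity
0,0,1,1
0.1,0.581,0.9324,0.99665
0.2,1.1554,0.9245,0.99336
0.3,1.7231,0.9215,0.99009
0.4,2.2843,0.9203,0.98682
0.5,2.8392,0.9209,0.98355
0.6,3.3878,0.923,0.98024
0.7,3.9302,0.9257,0.97692
0.8,4.4666,0.9288,0.97358
0.9,4.997,0.932,0.97023
1,5.5216,0.9355,0.96686
1.2,6.5535,0.9428,0.96006
1.4,7.5632,0.9513,0.95315
1.6,8.5513,0.9616,0.94607
1.8,9.5184,0.9723,0.93889
2,10.4653,0.9833,0.9316
2.5,12.7481,1.0146,0.91266
3,14.9174,1.0453,0.89316
3.5,16.9815,1.0764,0.87307
4,18.9477,1.1081,0.8524
4.5,20.823,1.1398,0.83127
5,22.6135,1.1708,0.80984
5.5,24.3248,1.2004,0.7883
6,25.962,1.2286,0.76675
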
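# Water activity of aqueous KCl at 25 C
# a_w = exp(-2 * phi * m * M_w / 1000), M_w = 18.015 g/mol, M(KCl) = 74.551 g/mol
# Osmotic coefficients phi: approximate values compiled from standard
# compilations (Robinson & Stokes 1959; Hamer & Wu 1972), 25 C.
# m = 0 row is the pure-water limit (phi formally 1).
molality,mass_fraction_pct,osmotic_coefficient,water_activity
0,0,1,1
0.1,0.74,0.9266,0.99667
0.2,1.4691,0.913,0.99344
0.3,2.1876,0.9063,0.99025
0.4,2.8957,0.9017,0.98709
0.5,3.5936,0.8989,0.98394
0.6,4.2815,0.8976,0.98078
0.7,4.9597,0.897,0.97763
0.8,5.6284,0.8971,0.97447
0.9,6.2877,0.8976,0.97131
1,6.9379,0.8984,0.96815
1.2,8.2115,0.901,0.96179
1.4,9.4508,0.9042,0.95541
1.6,10.657,0.9081,0.949
1.8,11.8315,0.9124,0.94254
2,12.9755,0.9168,0.93607
2.5,15.7098,0.9284,0.91978
3,18.2775,0.9402,0.90337
3.5,20.6934,0.9521,0.88686
4,22.9705,0.9639,0.8703
4.5,25.1205,0.9756,0.8537
4.8,26.3539,0.9826,0.84372
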
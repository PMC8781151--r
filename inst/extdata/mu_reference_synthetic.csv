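# SYNTHETIC reference table of water/ice chemical potential vs temperature
# (J/mol, relative to the triple point of water, 273.16 K at 611.657 Pa).
# Constructed as a stand-in for published tabulations that are not
# redistributable here; values carry a small deterministic ripple so that
# quadratic re-fitting is a meaningful exercise. Not measured data.
phase,temperature_C,mu_J_per_mol
water,0,8.038
water,5,1.265
water,10,-11.375
water,15,-29.898
water,20,-54.298
water,25,-84.546
water,30,-120.609
water,35,-162.462
water,40,-210.104
water,45,-263.554
water,50,-322.846
water,55,-388.011
water,60,-459.059
water,65,-535.979
water,70,-618.74
water,75,-707.311
water,80,-801.669
water,85,-901.818
water,90,-1007.781
water,95,-1119.594
water,100,-1237.283
ice,-25,-589.129
ice,-22.5,-525.148
ice,-20,-462.076
ice,-17.5,-399.91
ice,-15,-338.644
ice,-12.5,-278.272
ice,-10,-218.789
ice,-7.5,-160.192
ice,-5,-102.479
ice,-2.5,-45.651
ice,0,10.286
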